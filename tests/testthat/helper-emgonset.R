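# shared fixtures, built in code and cached across tests within a run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# short-trial protocol for fast tests (structure preserved, durations halved)
fast_timing <- function() protocol_timing(T = 8, T_ON = 4, T_R1 = 2)

fast_config <- function(...) {
  synth_config(timing = fast_timing(), n_trials = 4, n_sessions = 2,
               lead_in = 2, seed = 11, ...)
}

fast_session <- function(session = 1, key = paste0("fast", session)) {
  cached(key, simulate_session(fast_config(), session))
}

# preprocessed features + segmentation for the default fast session
fast_prepared <- function(session = 1) {
  cached(paste0("prep", session), {
    ss <- fast_session(session)
    rec <- preprocess_recording(ss$recording)
    trials <- add_reference_onsets(rec, segment_trials(rec, fast_timing()))
    list(rec = rec, trials = trials,
         features = feature_matrix(rec), truth = ss$truth)
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
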