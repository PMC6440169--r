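# build a bare single-trial recording with analytic kinematics
analytic_trial <- function(move_amp = c(10, 40, 8, 35), D = 1,
                           t_on = 3, noise = 0) {
  fs <- 1000
  n <- 8 * fs
  t <- (seq_len(n) - 1) / fs
  mj <- function(tau) {
    tau <- pmin(pmax(tau, 0), 1)
    10 * tau^3 - 15 * tau^4 + 6 * tau^5
  }
  ang <- sapply(move_amp, function(A) A * mj((t - t_on) / D) +
                  rnorm(n, 0, noise))
  colnames(ang) <- c("sAA", "sFE", "sIE", "eFE")
  rec <- emg_recording(matrix(rnorm(n * 7, 0, 1e-6), n, 7), ang,
                       rep(0, n), rep(0L, n), rep(0L, n), fs, t)
  trial <- list(trial_index = 1, event = "GoForward",
                rest_interval = c(1L, as.integer(t_on * fs - 500)),
                movement_interval = c(as.integer(t_on * fs - 499L) + 500L,
                                      n + 1L),
                rest_time = c(0, t_on - 0.5), movement_time = c(t_on - 0.5,
                                                               8),
                truncated = FALSE, t0_reference = NA_real_)
  list(rec = rec, trial = trial, mj = mj, t_on = t_on, D = D)
}

test_that("kinematic reference onset matches the analytic 10% crossing", {
  set.seed(201)
  a <- analytic_trial()
  t0 <- reference_onset(a$rec, a$trial)
  u10 <- uniroot(function(u) a$mj(u) - 0.1, c(0, 1), tol = 1e-12)$root
  expect_lt(abs(t0 - (a$t_on + a$D * u10)), 1.5e-3)  # within ~1 sample
})

test_that("torque-threshold reference onset lands on the crossing sample", {
  fs <- 1000
  n <- 4000
  t <- (seq_len(n) - 1) / fs
  tq <- pmax(0, (t - 2) * 4)  # reaches 2 N·m exactly at t = 2.5
  rec <- emg_recording(matrix(0, n, 7), matrix(0, n, 4), tq,
                       rep(0L, n), rep(0L, n), fs, t)
  trial <- list(event = "GoBackward", movement_interval = c(2001L, 3501L),
                rest_interval = c(1001L, 2001L))
  expect_equal(as.numeric(reference_onset(rec, trial)), 2.5)
})

test_that("flat kinematics are flagged unscorable", {
  set.seed(202)
  a <- analytic_trial(move_amp = c(0, 0, 0, 0), noise = 0.01)
  t0 <- reference_onset(a$rec, a$trial)
  expect_true(is.na(t0))
  expect_true(attr(t0, "unscorable"))
})

# construct a label/onset stream and matching trials directly
synthetic_scoring_case <- function(n_trials = 10, step = 0.01) {
  t0s <- 5 + 12 * (seq_len(n_trials) - 1)
  trials <- lapply(seq_len(n_trials), function(k) {
    list(trial_index = k, event = "GoForward",
         rest_time = c(t0s[k] - 4, t0s[k] - 1),
         movement_time = c(t0s[k], t0s[k] + 2),
         rest_interval = c(1L, 2L), movement_interval = c(2L, 3L),
         truncated = FALSE, t0_reference = t0s[k])
  })
  times <- seq(0, max(t0s) + 4, by = step)
  list(trials = trials, times = times, t0s = t0s)
}

test_that("the oracle detector scores 100/100 with zero latency", {
  sc <- synthetic_scoring_case()
  labels <- integer(length(sc$times))
  for (t0 in sc$t0s)
    labels[sc$times >= t0 & sc$times < t0 + 2] <- 1L
  result <- list(labels = labels, times = sc$times, onsets = sc$t0s)
  rep_ <- score_detector(result, sc$trials)
  expect_identical(rep_$sensitivity, 100)
  expect_identical(rep_$specificity, 100)
  expect_identical(rep_$latency_median, 0)
  expect_identical(rep_$latency_mean, 0)
})

test_that("hand-constructed counts give sensitivity 80.0, specificity 97.0", {
  sc <- synthetic_scoring_case(10)
  # onsets for 8 of 10 trials inside the acceptance window
  onsets <- sc$t0s[1:8] + 0.05
  # labels: exactly 1000 rest-phase steps, 30 labelled movement
  labels <- integer(length(sc$times))
  rest_idx <- which(vapply(sc$times, function(tt)
    any(vapply(sc$trials, function(tr)
      tt >= tr$rest_time[1] && tt < tr$rest_time[2], logical(1))),
    logical(1)))
  rest_idx <- rest_idx[1:1000]
  labels[rest_idx[1:30]] <- 1L
  times_sub <- sc$times[rest_idx]
  result <- list(labels = labels[rest_idx], times = times_sub,
                 onsets = onsets)
  rep_ <- score_detector(result, sc$trials)
  expect_identical(rep_$TP, 8L)
  expect_identical(rep_$FN, 2L)
  expect_identical(rep_$sensitivity, 80)
  expect_identical(rep_$TN, 970L)
  expect_identical(rep_$FP, 30L)
  expect_identical(rep_$specificity, 97)
})

test_that("constant anticipation appears as negative median latency", {
  sc <- synthetic_scoring_case()
  result <- list(labels = integer(length(sc$times)), times = sc$times,
                 onsets = sc$t0s - 0.1)
  rep_ <- score_detector(result, sc$trials)
  expect_equal(rep_$latency_median, -0.1)
})

test_that("metrics are invariant to a common time shift", {
  sc <- synthetic_scoring_case()
  labels <- as.integer(seq_along(sc$times) %% 37 == 0)
  res <- list(labels = labels, times = sc$times, onsets = sc$t0s + 0.2)
  r1 <- score_detector(res, sc$trials)
  shift <- 11.5
  trials2 <- lapply(sc$trials, function(tr) {
    tr$rest_time <- tr$rest_time + shift
    tr$movement_time <- tr$movement_time + shift
    tr$t0_reference <- tr$t0_reference + shift
    tr
  })
  res2 <- list(labels = labels, times = sc$times + shift,
               onsets = res$onsets + shift)
  r2 <- score_detector(res2, trials2)
  expect_identical(r1$sensitivity, r2$sensitivity)
  expect_identical(r1$specificity, r2$specificity)
  expect_equal(r1$latencies, r2$latencies)
})

test_that("sensitivity never increases when the window shrinks", {
  sc <- synthetic_scoring_case()
  set.seed(203)
  res <- list(labels = integer(length(sc$times)), times = sc$times,
              onsets = sc$t0s + rnorm(10, 0, 0.6))
  wide <- score_detector(res, sc$trials, t_pre = 1, t_post = 1.5)
  narrow <- score_detector(res, sc$trials, t_pre = 0.2, t_post = 0.3)
  expect_lte(narrow$sensitivity, wide$sensitivity)
  expect_error(score_detector(res, list()), "no scorable trials")
})

test_that("two-session cross-validation runs both rotations, reproducibly", {
  sessions <- list(fast_session(1)$recording, fast_session(2)$recording)
  cfg <- detector_config("Type1", muscle = "AnteriorDeltoid")
  cv1 <- session_cross_validation(sessions, cfg, event = "GoForward",
                                  timing = fast_timing())
  expect_equal(cv1$n_rotations, 2)
  expect_identical(sort(cv1$rotations$train), c(1, 2))
  cv2 <- session_cross_validation(sessions, cfg, event = "GoForward",
                                  timing = fast_timing())
  expect_identical(cv1$rotations, cv2$rotations)
  expect_identical(cv1$latencies, cv2$latencies)
})

test_that("identical sessions cross-validate to identical rotations", {
  rec <- fast_session(1)$recording
  cv <- session_cross_validation(list(rec, rec, rec),
                                 detector_config("Type1",
                                                 muscle = "Biceps"),
                                 timing = fast_timing())
  expect_equal(cv$n_rotations, 6)
  expect_equal(length(unique(cv$rotations$sensitivity)), 1)
  expect_equal(length(unique(cv$rotations$specificity)), 1)
})

test_that("information-performance correlation behaves like Pearson r", {
  perf <- c(10, 20, 30, 40, 50)
  info <- cbind(A = perf * 0.01 + 0.1, B = -perf * 0.02 + 2)
  out <- correlate_info_performance(perf, info)
  expect_equal(out$r, c(1, -1), tolerance = 1e-12)
  # affine invariance
  out2 <- correlate_info_performance(3 * perf + 7, info)
  expect_equal(out$r, out2$r, tolerance = 1e-12)
  expect_error(correlate_info_performance(perf[1:2], info[1:2, ]),
               "at least 3")
})
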