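#' Configuration of the synthetic reaching-session generator
#'
#' Generates protocol-faithful surrogate sessions: amplitude-modulated
#' Gaussian noise as the sEMG model (burst gains multiply the per-channel
#' rest noise level during activation), minimum-jerk joint-angle reach and
#' return profiles, a torque ramp crossing the protocol threshold at the
#' return initiation, and LED/control-mode timelines. Defaults mirror the
#' cued-reaching protocol: 12 s trials (LED on 6 s, transparent for 2.5 s
#' then position control), 24 trials per session, 7 sessions, 1 kHz.
#'
#' @param timing a [protocol_timing].
#' @param n_trials trials per session (default 24).
#' @param n_sessions sessions per subject (default 7).
#' @param sample_rate Hz (default 1000).
#' @param reaction_mean,reaction_sd reaction time to the LED cue, s
#'   (default 0.30 / 0.05, truncated below `reaction_min`).
#' @param reaction_min lower truncation of the reaction time, s.
#' @param emd electromechanical delay between EMG and kinematic onset, s
#'   (default 0.08).
#' @param move_duration,return_duration minimum-jerk movement times, s.
#' @param sigma_rest per-channel rest noise SD, volts (default 8e-6).
#' @param gains_forward,gains_backward per-muscle burst gains (multiples of
#'   the rest SD) for the two events; 1 = silent.
#' @param hold_frac fraction of the forward gain excess retained while the
#'   target posture is held (residual activation, default 0.1).
#' @param envelope `"raised_cosine"` or `"trapezoid"` burst edges.
#' @param ramp envelope rise/fall time, s (default 0.15).
#' @param drift fractional rest-noise growth over one session (default 0;
#'   0.5 means the rest SD ends 50% higher than it started).
#' @param mains_amp 50 Hz interference amplitude, volts (default 0).
#' @param angle_amplitude per-joint reach amplitudes, degrees.
#' @param angle_noise_sd angle measurement noise SD, degrees.
#' @param torque_peak peak return torque, N·m (default 5).
#' @param torque_rise torque ramp rise time, s (default 0.4).
#' @param lead_in initial rest before the first trial, s (default 3).
#' @param seed integer seed; sessions are reproducible from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(timing = protocol_timing(), n_trials = 24,
                         n_sessions = 7, sample_rate = 1000,
                         reaction_mean = 0.30, reaction_sd = 0.05,
                         reaction_min = 0.1, emd = 0.08,
                         move_duration = 1.0, return_duration = 1.0,
                         sigma_rest = 8e-6,
                         gains_forward = c(Trapezius = 1.8,
                                           AnteriorDeltoid = 4.0,
                                           PosteriorDeltoid = 3.2,
                                           Biceps = 2.6, Triceps = 1.4,
                                           FlexorCarpiUlnaris = 1.0,
                                           ExtensorCarpiUlnaris = 1.0),
                         gains_backward = c(Trapezius = 1.2,
                                            AnteriorDeltoid = 1.4,
                                            PosteriorDeltoid = 1.2,
                                            Biceps = 2.8, Triceps = 1.3,
                                            FlexorCarpiUlnaris = 1.0,
                                            ExtensorCarpiUlnaris = 3.6),
                         hold_frac = 0.1,
                         envelope = c("raised_cosine", "trapezoid"),
                         ramp = 0.15, drift = 0, mains_amp = 0,
                         angle_amplitude = c(sAA = 12, sFE = 40,
                                             sIE = 8, eFE = 35),
                         angle_noise_sd = 0.02,
                         torque_peak = 5, torque_rise = 0.4,
                         lead_in = 3, seed = 1) {
  stopifnot(inherits(timing, "protocol_timing"))
  envelope <- match.arg(envelope)
  if (any(gains_forward < 1) || any(gains_backward < 1))
    stop("burst gains must be >= 1 (1 = silent muscle)")
  if (reaction_min <= 0 || emd < 0) stop("invalid reaction/delay settings")
  if (length(sigma_rest) == 1)
    sigma_rest <- stats::setNames(rep(sigma_rest, length(EMG_CHANNELS)),
                                  EMG_CHANNELS)
  structure(as.list(environment()), class = "synth_config")
}

# smooth unit burst on [t_on, t_off] with rise/fall time `ramp`
burst_envelope <- function(t, t_on, t_off, ramp,
                           shape = "raised_cosine") {
  e <- numeric(length(t))
  up <- t >= t_on & t < t_on + ramp
  mid <- t >= t_on + ramp & t <= t_off - ramp
  dn <- t > t_off - ramp & t <= t_off
  if (shape == "raised_cosine") {
    e[up] <- 0.5 * (1 - cos(pi * (t[up] - t_on) / ramp))
    e[dn] <- 0.5 * (1 - cos(pi * (t_off - t[dn]) / ramp))
  } else {
    e[up] <- (t[up] - t_on) / ramp
    e[dn] <- (t_off - t[dn]) / ramp
  }
  e[mid] <- 1
  e
}

# minimum-jerk position profile, s(0) = 0, s(1) = 1
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# fraction of the rise time at which a minimum-jerk ramp reaches `frac`
min_jerk_inv <- function(frac) {
  stats::uniroot(function(u) min_jerk(u) - frac, c(0, 1),
                 tol = 1e-12)$root
}

#' Simulate one synthetic session with ground truth
#'
#' @param config a [synth_config].
#' @param session session index (1-based); offsets the RNG stream so each
#'   session is distinct but reproducible.
#' @param subject_id,session_id identifiers for the recording.
#' @return list with `recording` (an [emg_recording]) and `truth` (see
#'   Details).
#' @details `truth$trials` is a data.frame with one row per trial:
#'   `trial`, `t_led_on_s`, `t_led_off_s`, per-event EMG onsets
#'   (`t_emg_fwd_s`, `t_emg_bwd_s`), the kinematic onset `t_kin_onset_s`
#'   (forward) and the torque-crossing time `t_torque_cross_s` (backward);
#'   muscle activity always precedes the kinematic/torque reference
#'   (electromechanical delay). `truth$move_end_fwd_s` /
#'   `truth$move_end_bwd_s` give the burst end times used for phase labels.
#' @export
simulate_session <- function(config = synth_config(), session = 1,
                             subject_id = "synthetic",
                             session_id = paste0("sess", session)) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  set.seed((cf$seed %% 2147480) * 1000L + session)
  fs <- cf$sample_rate
  tm <- cf$timing
  T_total <- cf$lead_in + cf$n_trials * tm$T
  n <- round(T_total * fs)
  t <- (seq_len(n) - 1) / fs
  led_on <- cf$lead_in + (seq_len(cf$n_trials) - 1) * tm$T
  led_off <- led_on + tm$T_ON
  rt <- function(k) pmax(rnorm(k, cf$reaction_mean, cf$reaction_sd),
                         cf$reaction_min)
  emg_fwd <- led_on + rt(cf$n_trials)
  kin_on <- emg_fwd + cf$emd
  emg_bwd <- led_off + rt(cf$n_trials)
  tq_cross <- emg_bwd + cf$emd
  move_end_f <- kin_on + cf$move_duration + cf$ramp
  move_end_b <- tq_cross + cf$return_duration + cf$ramp
  # envelopes shared across channels (per event), plus residual hold tone
  env_f <- numeric(n); env_b <- numeric(n); env_h <- numeric(n)
  for (k in seq_len(cf$n_trials)) {
    env_f <- env_f + burst_envelope(t, emg_fwd[k], move_end_f[k],
                                    cf$ramp, cf$envelope)
    env_b <- env_b + burst_envelope(t, emg_bwd[k], move_end_b[k],
                                    cf$ramp, cf$envelope)
    env_h <- env_h + burst_envelope(t, move_end_f[k], emg_bwd[k] + cf$ramp,
                                    cf$ramp, cf$envelope)
  }
  drift_fac <- 1 + cf$drift * t / T_total
  emg <- matrix(0, n, length(EMG_CHANNELS),
                dimnames = list(NULL, EMG_CHANNELS))
  for (ch in EMG_CHANNELS) {
    gf <- cf$gains_forward[[ch]]; gb <- cf$gains_backward[[ch]]
    gh <- 1 + cf$hold_frac * (gf - 1)
    sig <- cf$sigma_rest[[ch]] * drift_fac *
      (1 + (gf - 1) * env_f + (gb - 1) * env_b + (gh - 1) * env_h)
    emg[, ch] <- sig * rnorm(n)
    if (cf$mains_amp > 0)
      emg[, ch] <- emg[, ch] +
        cf$mains_amp * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
  }
  # kinematics: minimum-jerk reach at kin_on, return after torque crossing
  ang <- matrix(0, n, length(JOINT_NAMES),
                dimnames = list(NULL, JOINT_NAMES))
  pos_frac <- numeric(n)
  for (k in seq_len(cf$n_trials)) {
    reach <- min_jerk((t - kin_on[k]) / cf$move_duration)
    ret <- min_jerk((t - tq_cross[k]) / cf$return_duration)
    pos_frac <- pos_frac + reach - ret
  }
  pos_frac <- pmin(pmax(pos_frac, 0), 1)
  for (j in JOINT_NAMES)
    ang[, j] <- cf$angle_amplitude[[j]] * pos_frac +
      rnorm(n, 0, cf$angle_noise_sd)
  # torque: minimum-jerk ramp placed to cross tau_thr at tq_cross exactly
  tq <- numeric(n)
  u_star <- min_jerk_inv(tm$tau_thr / cf$torque_peak)
  for (k in seq_len(cf$n_trials)) {
    t_start <- tq_cross[k] - cf$torque_rise * u_star
    rise <- min_jerk((t - t_start) / cf$torque_rise)
    fall <- min_jerk((t - (tq_cross[k] + 0.2)) / cf$torque_rise)
    tq <- tq + cf$torque_peak * (rise - fall)
  }
  tq <- tq + rnorm(n, 0, 0.005)
  led <- integer(n)
  ctrl <- integer(n)
  targets <- sample.int(3, cf$n_trials, replace = TRUE)
  for (k in seq_len(cf$n_trials)) {
    led[t >= led_on[k] & t < led_off[k]] <- targets[k]
    ctrl[t >= led_on[k] + tm$T_R1 & t < tq_cross[k]] <- 1L
  }
  rec <- emg_recording(emg, ang, tq, led, ctrl, sample_rate = fs,
                       time_s = t, subject_id = subject_id,
                       session_id = session_id)
  truth <- list(
    trials = data.frame(trial = seq_len(cf$n_trials),
                        t_led_on_s = led_on, t_led_off_s = led_off,
                        t_emg_fwd_s = emg_fwd, t_kin_onset_s = kin_on,
                        t_emg_bwd_s = emg_bwd,
                        t_torque_cross_s = tq_cross),
    move_end_fwd_s = move_end_f, move_end_bwd_s = move_end_b,
    config = cf, session = session)
  list(recording = rec, truth = truth)
}

#' Simulate a full synthetic subject (several sessions)
#'
#' @param config a [synth_config].
#' @param subject_id identifier.
#' @return list with `sessions` (list of [emg_recording]) and `truths`.
#' @export
simulate_subject <- function(config = synth_config(),
                             subject_id = "synthetic") {
  out <- lapply(seq_len(config$n_sessions), function(s)
    simulate_session(config, s, subject_id = subject_id))
  list(sessions = lapply(out, `[[`, "recording"),
       truths = lapply(out, `[[`, "truth"))
}

#' Ground-truth phase labels at the feature update rate
#'
#' @param truth `truth` component of [simulate_session()].
#' @param step_times window-end timestamps, s.
#' @param event `"GoForward"` or `"GoBackward"`.
#' @return integer vector 0 (rest) / 1 (movement) / `NA` (transition gap).
#' @export
ground_truth_labels <- function(truth, step_times, event) {
  lab <- rep(NA_integer_, length(step_times))
  tr <- truth$trials
  cf <- truth$config
  for (k in seq_len(nrow(tr))) {
    if (event == "GoForward") {
      r0 <- tr$t_led_on_s[k] - min(3, cf$timing$T_OFF / 2)
      lab[step_times >= r0 & step_times < tr$t_led_on_s[k]] <- 0L
      lab[step_times >= tr$t_emg_fwd_s[k] &
            step_times < truth$move_end_fwd_s[k]] <- 1L
    } else {
      lab[step_times >= truth$move_end_fwd_s[k] + cf$ramp &
            step_times < tr$t_led_off_s[k]] <- 0L
      lab[step_times >= tr$t_emg_bwd_s[k] &
            step_times < truth$move_end_bwd_s[k]] <- 1L
    }
  }
  lab
}

#' Write the ground-truth sidecar CSV
#'
#' @param truth `truth` component of [simulate_session()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  data.table::fwrite(truth$trials, path)
  invisible(path)
}
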