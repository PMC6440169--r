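#' Reaching-protocol timing parameters
#'
#' Timing of one trial of the cued reaching protocol: total duration `T`
#' split into an LED-on phase `T_ON` (free reach for `T_R1`, then the
#' exoskeleton holds the target posture in position control for `T_R2`) and
#' an LED-off phase `T_OFF` (return to rest). The return is initiated when
#' the elbow flexion/extension torque exceeds `tau_thr`.
#'
#' @param T trial duration, s.
#' @param T_ON LED-on duration, s.
#' @param T_R1 transparent-mode window after LED-on, s.
#' @param tau_thr torque threshold discriminating the voluntary return, N·m.
#' @return object of class `protocol_timing` (list with fields `T`, `T_ON`,
#'   `T_OFF`, `T_R1`, `T_R2`, `tau_thr`).
#' @export
protocol_timing <- function(T = 12, T_ON = 6, T_R1 = 2.5, tau_thr = 2) {
  T_OFF <- T - T_ON
  T_R2 <- T_ON - T_R1
  if (any(c(T, T_ON, T_OFF, T_R1, T_R2) <= 0))
    stop("protocol timing must satisfy 0 < T_R1 < T_ON < T")
  structure(list(T = T, T_ON = T_ON, T_OFF = T_OFF,
                 T_R1 = T_R1, T_R2 = T_R2, tau_thr = tau_thr),
            class = "protocol_timing")
}

#' Construct a synchronized multichannel recording
#'
#' Container for one experimental session: multichannel sEMG, the four
#' exoskeleton joint angles, elbow torque, LED state and control mode, all
#' sampled on a common time base.
#'
#' @param emg numeric matrix (samples x channels) of EMG, volts; column
#'   names are the muscle labels.
#' @param joint_angles numeric matrix (samples x 4), degrees, columns
#'   `sAA`, `sFE`, `sIE`, `eFE`.
#' @param torque_eFE numeric vector, N·m.
#' @param led_state integer vector (0 = off, 1 = W, 2 = C, 3 = E).
#' @param control_mode integer vector (0 = transparent, 1 = position).
#' @param sample_rate sampling rate, Hz.
#' @param time_s optional time column, s; defaults to `(0:(n-1))/sample_rate`.
#' @param subject_id,session_id identifiers.
#' @param strict require exactly the seven protocol muscles.
#' @return object of class `emg_recording`.
#' @export
emg_recording <- function(emg, joint_angles, torque_eFE, led_state,
                          control_mode, sample_rate = 1000, time_s = NULL,
                          subject_id = "S1", session_id = "sess1",
                          strict = TRUE) {
  emg <- as.matrix(emg)
  joint_angles <- as.matrix(joint_angles)
  n <- nrow(emg)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) / sample_rate
  lens <- c(nrow(joint_angles), length(torque_eFE), length(led_state),
            length(control_mode), length(time_s))
  if (any(lens != n))
    stop("all time series must share one length (", n, " samples)")
  if (is.null(colnames(emg)))
    colnames(emg) <- EMG_CHANNELS[seq_len(ncol(emg))]
  if (anyDuplicated(colnames(emg)))
    stop("duplicate EMG channel names")
  if (strict && !identical(colnames(emg), EMG_CHANNELS))
    stop("strict mode expects the 7 protocol muscles in order: ",
         paste(EMG_CHANNELS, collapse = ", "))
  if (is.null(colnames(joint_angles)))
    colnames(joint_angles) <- JOINT_NAMES[seq_len(ncol(joint_angles))]
  for (v in list(led_state, control_mode))
    if (any(abs(v - round(v)) > 1e-9))
      stop("led_state and control_mode must be integer codes")
  structure(list(sample_rate = sample_rate, time_s = as.numeric(time_s),
                 emg = emg, channel_names = colnames(emg),
                 joint_angles = joint_angles,
                 torque_eFE = as.numeric(torque_eFE),
                 led_state = as.integer(round(led_state)),
                 control_mode = as.integer(round(control_mode)),
                 subject_id = subject_id, session_id = session_id),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("emg_recording:", x$subject_id, "/", x$session_id, "\n")
  cat("  ", nrow(x$emg), "samples at", x$sample_rate, "Hz (",
      round(nrow(x$emg) / x$sample_rate, 2), "s )\n")
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat("  LED-on episodes:", sum(diff(c(0L, x$led_state > 0L)) == 1L), "\n")
  invisible(x)
}

REC_COLUMNS <- c("time_s", paste0("emg_", EMG_CHANNELS),
                 paste0("angle_", JOINT_NAMES, "_deg"),
                 "torque_eFE_Nm", "led_state", "control_mode")

#' Write a recording to the session CSV dialect
#'
#' UTF-8 comma-separated file with a `#`-prefixed metadata header
#' (`subject_id`, `session_id`, `sample_rate`) followed by one row per
#' sample with the documented column set.
#'
#' @param rec an [emg_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  dt <- data.table::data.table(time_s = rec$time_s)
  for (ch in rec$channel_names) dt[[paste0("emg_", ch)]] <- rec$emg[, ch]
  for (j in colnames(rec$joint_angles))
    dt[[paste0("angle_", j, "_deg")]] <- rec$joint_angles[, j]
  dt[["torque_eFE_Nm"]] <- rec$torque_eFE
  dt[["led_state"]] <- rec$led_state
  dt[["control_mode"]] <- rec$control_mode
  hdr <- c(paste0("# subject_id: ", rec$subject_id),
           paste0("# session_id: ", rec$session_id),
           paste0("# sample_rate: ", format(rec$sample_rate, digits = 15)))
  writeLines(hdr, path)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a recording from the session CSV dialect
#'
#' @param path session CSV file (see [write_recording] for the dialect).
#' @param strict require the full 7-muscle protocol column set.
#' @return an [emg_recording].
#' @export
read_recording <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  top <- readLines(path, n = 50L)
  meta_lines <- top[startsWith(top, "#")]
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  dt <- data.table::fread(path, skip = length(meta_lines), header = TRUE,
                          data.table = FALSE)
  need <- if (strict) REC_COLUMNS else
    c("time_s", "led_state", "control_mode")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.unsorted(dt$time_s, strictly = TRUE))
    stop("time_s column is not strictly increasing")
  sr <- as.numeric(meta$sample_rate %||%
                     (1 / stats::median(diff(dt$time_s))))
  emg_cols <- grep("^emg_", names(dt), value = TRUE)
  ang_cols <- grep("^angle_.*_deg$", names(dt), value = TRUE)
  emg <- as.matrix(dt[emg_cols])
  colnames(emg) <- sub("^emg_", "", emg_cols)
  ang <- as.matrix(dt[ang_cols])
  colnames(ang) <- sub("_deg$", "", sub("^angle_", "", ang_cols))
  emg_recording(emg, ang, dt$torque_eFE_Nm %||% rep(0, nrow(dt)),
                dt$led_state, dt$control_mode,
                sample_rate = sr, time_s = dt$time_s,
                subject_id = meta$subject_id %||% "unknown",
                session_id = meta$session_id %||% "unknown",
                strict = strict)
}

#' Segment a session into per-trial rest/movement phases
#'
#' Each LED-on episode yields two scored transitions: *GoForward* (rest
#' before the LED cue, movement from the cue until the exoskeleton engages
#' position control) and *GoBackward* (rest while the posture is held in
#' position control, movement from LED-off until the return completes).
#' Intervals are half-open `[start, end)` sample index pairs (1-based).
#'
#' @param rec an [emg_recording].
#' @param timing a [protocol_timing].
#' @param drop_truncated drop (instead of flag) trials cut by the end of the
#'   recording or with an LED-on phase shorter than `T_R1`.
#' @param return_window duration after LED-off labelled as GoBackward
#'   movement, s (default 2; capped at `T_OFF/2`). The return movement
#'   completes well within this window, and a tighter window keeps the
#'   movement phase from absorbing post-return quiescence.
#' @return list of trial segmentations, each a list with `trial_index`,
#'   `event`, `rest_interval`, `movement_interval` (sample index pairs),
#'   `rest_time`, `movement_time` (seconds), `truncated`, `t0_reference`.
#' @export
segment_trials <- function(rec, timing = protocol_timing(),
                           drop_truncated = FALSE, return_window = 2) {
  stopifnot(inherits(rec, "emg_recording"))
  fs <- rec$sample_rate
  n <- length(rec$led_state)
  on <- as.integer(rec$led_state > 0L)
  d <- diff(c(0L, on))
  starts <- which(d == 1L)
  if (!length(starts)) stop("no LED off->on transition in recording")
  ends <- which(diff(c(on, 0L)) == -1L)  # last on-sample of each episode
  out <- list()
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- ends[k]
    off_idx <- e + 1L                    # first LED-off sample
    nxt <- if (k < length(starts)) starts[k + 1L] else n + 1L
    truncated <- (e - s + 1L) < floor(timing$T_R1 * fs) || off_idx > n
    # position-control engagement within the episode
    pos <- which(rec$control_mode[s:min(e, n)] == 1L)
    pos_idx <- if (length(pos)) s + pos[1L] - 1L else
      min(s + round(timing$T_R1 * fs), e + 1L)
    rest_len <- round(min(timing$T_OFF / 2, 3) * fs)
    fw <- list(trial_index = k, event = "GoForward",
               rest_interval = c(max(1L, s - rest_len), s),
               movement_interval = c(s, pos_idx),
               truncated = truncated, t0_reference = NA_real_)
    bw_end <- min(off_idx + round(min(return_window, timing$T_OFF / 2) * fs),
                  nxt, n + 1L)
    bw <- list(trial_index = k, event = "GoBackward",
               rest_interval = c(pos_idx, min(off_idx, n + 1L)),
               movement_interval = c(min(off_idx, n + 1L), bw_end),
               truncated = truncated || off_idx > n || bw_end <= off_idx,
               t0_reference = NA_real_)
    for (tr in list(fw, bw)) {
      if (tr$truncated) {
        if (drop_truncated) next
        warning("trial ", k, " (", tr$event, ") is truncated", call. = FALSE)
      }
      if (diff(tr$rest_interval) <= 0 || diff(tr$movement_interval) <= 0)
        next
      tr$rest_time <- rec$time_s[pmin(tr$rest_interval, n)]
      tr$movement_time <- rec$time_s[pmin(tr$movement_interval, n)]
      out[[length(out) + 1L]] <- tr
    }
  }
  out
}
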