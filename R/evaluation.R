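#' Preprocess every EMG channel of a recording
#'
#' Applies [preprocess_emg()] (high-pass + notch, zero-phase) to each
#' channel and returns the recording with filtered EMG.
#'
#' @param rec an [emg_recording].
#' @param ... passed to [preprocess_emg()].
#' @return the recording with filtered `emg`.
#' @export
preprocess_recording <- function(rec, ...) {
  stopifnot(inherits(rec, "emg_recording"))
  for (ch in rec$channel_names)
    rec$emg[, ch] <- preprocess_emg(rec$emg[, ch], rec$sample_rate, ...)
  rec
}

#' Reference onset time of one trial
#'
#' *GoForward*: for each of the four joint angles, the excursion from the
#' trial's rest baseline is computed and the first instant it reaches 10%
#' of its own peak excursion within the movement window is found; the
#' reference onset is the earliest such instant across joints.
#' *GoBackward*: the first instant the elbow torque reaches the protocol
#' threshold (`tau_thr`, 2 N·m) after LED-off.
#'
#' @param rec the [emg_recording] the trial belongs to.
#' @param trial one segmentation from [segment_trials()].
#' @param timing a [protocol_timing] (for `tau_thr`).
#' @param noise_floor minimum peak excursion (degrees) for a joint to be
#'   scorable (default 0.5).
#' @return onset time `t_0` in seconds, or `NA` (with attribute
#'   `unscorable = TRUE`) if no signal crosses its criterion.
#' @export
reference_onset <- function(rec, trial, timing = protocol_timing(),
                            noise_floor = 0.5) {
  n <- nrow(rec$emg)
  mi <- trial$movement_interval
  idx <- seq.int(mi[1], min(mi[2] - 1L, n))
  if (trial$event == "GoForward") {
    ri <- trial$rest_interval
    ridx <- seq.int(ri[1], min(ri[2] - 1L, n))
    t0 <- Inf
    for (j in colnames(rec$joint_angles)) {
      base <- mean(rec$joint_angles[ridx, j])
      exc <- abs(rec$joint_angles[idx, j] - base)
      pk <- max(exc)
      if (pk < noise_floor) next
      k <- which(exc >= 0.1 * pk)[1]
      if (!is.na(k)) t0 <- min(t0, rec$time_s[idx[k]])
    }
    if (is.infinite(t0))
      return(structure(NA_real_, unscorable = TRUE))
    t0
  } else {
    k <- which(rec$torque_eFE[idx] >= timing$tau_thr)[1]
    if (is.na(k)) return(structure(NA_real_, unscorable = TRUE))
    rec$time_s[idx[k]]
  }
}

#' Fill reference onsets for all trials of a session
#'
#' @param rec an [emg_recording].
#' @param trials segmentations from [segment_trials()].
#' @param timing a [protocol_timing].
#' @param ... passed to [reference_onset()].
#' @return `trials` with `t0_reference` filled (NA when unscorable).
#' @export
add_reference_onsets <- function(rec, trials, timing = protocol_timing(),
                                 ...) {
  lapply(trials, function(tr) {
    tr$t0_reference <- as.numeric(reference_onset(rec, tr, timing, ...))
    tr
  })
}

#' Score a detector against reference onsets
#'
#' Event-wise sensitivity: a trial is a true positive when at least one
#' detected onset falls within `[t_0 - t_pre, t_0 + t_post]` of its
#' reference onset, otherwise a false negative; the latency of a detected
#' trial is the first qualifying onset minus `t_0` (negative =
#' anticipation). Sample-wise specificity: feature steps inside the
#' event's rest phases count as true negatives when labelled rest and as
#' false positives when labelled movement (the reaction gap between cue
#' and reference onset belongs to neither phase and is excluded).
#'
#' @param result a `detection_result` from [run_detector()] (or a list
#'   with `labels`, `times`, `onsets`).
#' @param trials segmentations with `t0_reference` filled
#'   ([add_reference_onsets()]).
#' @param event `"GoForward"` or `"GoBackward"`.
#' @param t_pre,t_post acceptance window around the reference onset, s
#'   (defaults 0.5 and 1.0).
#' @return object of class `performance_report`: counts `TP`, `FN`
#'   (trials), `TN`, `FP` (steps), `sensitivity` and `specificity` (%),
#'   `latency_mean`, `latency_median`, `latency_iqr` (s) and the per-trial
#'   `latencies`.
#' @export
score_detector <- function(result, trials, event = "GoForward",
                           t_pre = 0.5, t_post = 1.0) {
  trs <- Filter(function(tr) tr$event == event && !isTRUE(tr$truncated) &&
                  is.finite(tr$t0_reference), trials)
  if (!length(trs)) stop("no scorable trials for event ", event)
  TP <- 0L; FN <- 0L
  lat <- numeric(0)
  for (tr in trs) {
    t0 <- tr$t0_reference
    q <- result$onsets[result$onsets >= t0 - t_pre &
                         result$onsets <= t0 + t_post]
    if (length(q)) {
      TP <- TP + 1L
      lat <- c(lat, q[1] - t0)
    } else FN <- FN + 1L
  }
  rest <- rep(FALSE, length(result$times))
  for (tr in trs)
    rest <- rest | (result$times >= tr$rest_time[1] &
                      result$times < tr$rest_time[2])
  TN <- sum(result$labels[rest] == 0L)
  FP <- sum(result$labels[rest] == 1L)
  structure(list(event = event,
                 detector = if (!is.null(result$config))
                   result$config$type else "custom",
                 TP = TP, FN = FN, TN = TN, FP = FP,
                 sensitivity = 100 * TP / (TP + FN),
                 specificity = if (TN + FP > 0)
                   100 * TN / (TN + FP) else NA_real_,
                 latency_mean = if (length(lat)) mean(lat) else NA_real_,
                 latency_median = if (length(lat)) median(lat) else NA_real_,
                 latency_iqr = if (length(lat))
                   unname(quantile(lat, c(0.25, 0.75))) else
                     c(NA_real_, NA_real_),
                 latencies = lat, n_trials = length(trs),
                 t_pre = t_pre, t_post = t_post),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("performance_report [%s, %s]\n", x$event, x$detector))
  cat(sprintf("  trials: %d  TP %d  FN %d   rest steps: TN %d  FP %d\n",
              x$n_trials, x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  latency mean %.3f s, median %.3f s, IQR [%.3f, %.3f] s\n",
              x$latency_mean, x$latency_median,
              x$latency_iqr[1], x$latency_iqr[2]))
  invisible(x)
}

#' Fit per-(muscle, feature) mixtures on a training session
#'
#' @param features named list of `feature_series` (per muscle).
#' @param muscles,feature_set which models to fit (defaults: all muscles,
#'   [default_feature_set()]).
#' @param ... passed to [emg_gmm()].
#' @return nested list `models[[muscle]][[feature]]` of `emg_gmm` fits.
#' @export
train_models <- function(features, muscles = names(features),
                         feature_set = default_feature_set(), ...) {
  models <- list()
  for (m in muscles) for (f in feature_set)
    models[[m]][[f]] <- emg_gmm(features[[m]]$values[, f], ...)
  models
}

#' Session-wise cross-validation of a detector
#'
#' Rotates over sessions: each session in turn provides the training data
#' for the per-(muscle, feature) mixtures, and the detector is tested on
#' every remaining session; outcome measures are averaged over rotations.
#'
#' @param sessions list of raw [emg_recording]s (one subject).
#' @param config a [detector_config].
#' @param event scored event (default `"GoForward"`).
#' @param spec a [window_spec].
#' @param timing a [protocol_timing].
#' @param L adaptive memory length (default 1000).
#' @param adapt `FALSE` freezes thresholds (ablation).
#' @param t_pre,t_post acceptance window, s.
#' @param preprocess apply [preprocess_recording()] first (default TRUE).
#' @return object of class `crossval_report`: per-rotation table
#'   (`rotations`), pooled `sensitivity`, `specificity` (means, %),
#'   `latency_median` (pooled, s), pooled `latencies`.
#' @export
session_cross_validation <- function(sessions, config,
                                     event = "GoForward",
                                     spec = window_spec(),
                                     timing = protocol_timing(),
                                     L = 1000, adapt = TRUE,
                                     t_pre = 0.5, t_post = 1.0,
                                     preprocess = TRUE) {
  if (length(sessions) < 2) stop("need at least 2 sessions")
  prep <- lapply(sessions, function(s) {
    r <- if (preprocess) preprocess_recording(s) else s
    trials <- segment_trials(r, timing)
    if (!length(trials)) return(NULL)
    list(features = feature_matrix(r, spec, names = config$features),
         trials = add_reference_onsets(r, trials, timing))
  })
  keep <- !vapply(prep, is.null, logical(1))
  if (any(!keep)) warning(sum(!keep), " session(s) without trials excluded")
  prep <- prep[keep]
  rot <- list()
  for (i in seq_along(prep)) {
    models <- train_models(prep[[i]]$features, muscles = config$muscles,
                           feature_set = config$features)
    for (j in seq_along(prep)) {
      if (j == i) next
      det <- run_detector(prep[[j]]$features, models, config, L = L,
                          adapt = adapt)
      rep_ <- score_detector(det, prep[[j]]$trials, event = event,
                             t_pre = t_pre, t_post = t_post)
      rot[[length(rot) + 1L]] <- list(train = i, test = j, report = rep_)
    }
  }
  sens <- vapply(rot, function(r) r$report$sensitivity, numeric(1))
  spcf <- vapply(rot, function(r) r$report$specificity, numeric(1))
  lats <- unlist(lapply(rot, function(r) r$report$latencies))
  structure(list(event = event, detector = config$type,
                 n_rotations = length(rot),
                 rotations = data.frame(
                   train = vapply(rot, `[[`, numeric(1), "train"),
                   test = vapply(rot, `[[`, numeric(1), "test"),
                   sensitivity = sens, specificity = spcf),
                 sensitivity = mean(sens), specificity = mean(spcf),
                 latency_median = median(lats),
                 latency_mean = mean(lats), latencies = lats,
                 reports = lapply(rot, `[[`, "report")),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("crossval_report [%s, %s]: %d rotations\n", x$event,
              x$detector, x$n_rotations))
  cat(sprintf("  mean sensitivity %.1f%%, mean specificity %.1f%%\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  latency median %.3f s (mean %.3f s, n = %d)\n",
              x$latency_median, x$latency_mean, length(x$latencies)))
  invisible(x)
}

#' Correlate detector performance with feature information
#'
#' Pearson correlation between per-unit detector performance (the product
#' sensitivity x specificity) and each feature's information content.
#'
#' @param performance numeric vector, one entry per (subject, session)
#'   unit.
#' @param info numeric matrix, units in rows, features in columns (bits).
#' @return data.frame with `feature`, `r`, `p`.
#' @export
correlate_info_performance <- function(performance, info) {
  info <- as.matrix(info)
  if (length(performance) < 3) stop("need at least 3 paired observations")
  if (nrow(info) != length(performance))
    stop("performance and info must be paired by row")
  out <- data.frame(feature = colnames(info), r = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(info))) {
    ct <- cor.test(performance, info[, i], method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out
}
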