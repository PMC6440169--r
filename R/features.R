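#' Sliding-window specification
#'
#' @param length_ms window length, ms (default 300).
#' @param step_ms update interval, ms (default 10).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(length_ms = 300, step_ms = 10) {
  if (step_ms > length_ms) stop("step must not exceed window length")
  if (length_ms <= 0 || step_ms <= 0) stop("window sizes must be positive")
  structure(list(length_ms = length_ms, step_ms = step_ms),
            class = "window_spec")
}

#' The registered time-domain EMG features
#'
#' @return character vector of the 14 feature identifiers.
#' @export
emg_features <- function() {
  c("IAV", "MAV", "MMAV1", "MMAV2", "SSI", "VAR", "RMS", "WL", "LOG",
    "ZC", "SSC", "WAMP", "AAC", "DASDV")
}

#' The operating feature subset used by the detectors
#'
#' The minimally redundant, synergistic subject-independent set selected by
#' the information-breakdown analysis.
#'
#' @return character vector `c("IAV", "SSI", "WL", "LOG")`.
#' @export
default_feature_set <- function() c("IAV", "SSI", "WL", "LOG")

LOG_FLOOR <- 1e-12  # volts; |x| clamp inside the LOG feature

mmav_weights <- function(N, which = c("MMAV1", "MMAV2")) {
  which <- match.arg(which)
  i <- seq_len(N)
  lo <- 0.25 * N; hi <- 0.75 * N
  if (which == "MMAV1") {
    w <- ifelse(i >= lo & i <= hi, 1, 0.5)
  } else {
    w <- rep(1, N)
    w[i < lo] <- 4 * i[i < lo] / N
    w[i > hi] <- 4 * (N - i[i > hi]) / N
  }
  w
}

#' Compute one time-domain feature on a signal window
#'
#' Scalar reference implementation of the 14 registered time-domain EMG
#' features. Amplitude features: IAV (integrated absolute value), MAV (mean
#' absolute value), MMAV1/MMAV2 (centre-weighted variants), SSI (simple
#' square integral), VAR, RMS, WL (waveform length), LOG (log detector,
#' `exp(mean(log|x|))` with `|x|` clamped at 1e-12 V), AAC (`WL/N`), DASDV.
#' Threshold-count features (threshold `eps`): ZC (sign changes), SSC
#' (slope-sign changes), WAMP (Willison amplitude).
#'
#' @param window numeric vector, the windowed samples (length >= 2).
#' @param name feature identifier, one of [emg_features()].
#' @param eps amplitude threshold for ZC/SSC/WAMP (same units as `window`).
#' @return scalar feature value.
#' @examples
#' compute_feature(c(1, -2, 3), "IAV")   # 6
#' compute_feature(c(1, -2, 3), "LOG")   # 6^(1/3)
#' @export
compute_feature <- function(window, name, eps = 0) {
  x <- as.numeric(window)
  N <- length(x)
  if (N < 2) stop("window must contain at least 2 samples")
  if (!name %in% emg_features())
    stop("unknown feature '", name, "'; registered features: ",
         paste(emg_features(), collapse = ", "))
  d <- diff(x)
  switch(name,
    IAV = sum(abs(x)),
    MAV = mean(abs(x)),
    MMAV1 = sum(mmav_weights(N, "MMAV1") * abs(x)) / N,
    MMAV2 = sum(mmav_weights(N, "MMAV2") * abs(x)) / N,
    SSI = sum(x^2),
    VAR = sum(x^2) / (N - 1),
    RMS = sqrt(mean(x^2)),
    WL = sum(abs(d)),
    LOG = {
      ax <- abs(x)
      if (any(ax < LOG_FLOOR)) {
        warning("LOG feature: |x| clamped at ", LOG_FLOOR, call. = FALSE)
        ax <- pmax(ax, LOG_FLOOR)
      }
      exp(mean(log(ax)))
    },
    ZC = sum(x[-N] * x[-1] < 0 & abs(d) >= eps),
    SSC = {
      if (N < 3) 0 else {
        xm <- x[2:(N - 1)]
        sum((xm - x[1:(N - 2)]) * (xm - x[3:N]) > 0 &
              pmax(abs(xm - x[1:(N - 2)]), abs(xm - x[3:N])) >= eps)
      }
    },
    WAMP = sum(abs(d) >= eps),
    AAC = sum(abs(d)) / N,
    DASDV = sqrt(sum(d^2) / (N - 1))
  )
}

# rolling sum over windows of `len` values starting at `starts` (cumsum trick)
roll_sum <- function(v, starts, len) {
  cs <- c(0, cumsum(v))
  cs[starts + len] - cs[starts]
}

# weighted rolling sum with in-window linear index weights i = 1..len,
# restricted to local index range [a, b]: sum_{i=a..b} i * v[start+i-1]
roll_sum_ramp <- function(v, starts, a, b) {
  if (b < a) return(rep(0, length(starts)))
  j <- seq_along(v)
  cs <- c(0, cumsum(v))
  csj <- c(0, cumsum(j * v))
  from <- starts + a - 1L; to <- starts + b - 1L
  (csj[to + 1L] - csj[from]) - (starts - 1) * (cs[to + 1L] - cs[from])
}

feature_windows <- function(x, N, step, eps, names) {
  n <- length(x)
  starts <- seq.int(1L, n - N + 1L, by = step)
  ax <- abs(x)
  d <- diff(x)
  ad <- abs(d)
  K <- length(starts)
  out <- matrix(NA_real_, K, length(names), dimnames = list(NULL, names))
  lo <- ceiling(0.25 * N); hi <- floor(0.75 * N)
  need <- function(nm) nm %in% names
  if (need("IAV") || need("MAV"))
    s_abs <- roll_sum(ax, starts, N)
  if (need("SSI") || need("VAR") || need("RMS"))
    s_sq <- roll_sum(x^2, starts, N)
  if (need("WL") || need("AAC"))
    s_wl <- roll_sum(ad, starts, N - 1L)
  for (nm in names) {
    out[, nm] <- switch(nm,
      IAV = s_abs,
      MAV = s_abs / N,
      MMAV1 = {
        full <- roll_sum(ax, starts, N)
        inner <- roll_sum(ax, starts + lo - 1L, hi - lo + 1L)
        (0.5 * full + 0.5 * inner) / N
      },
      MMAV2 = {
        inner <- roll_sum(ax, starts + lo - 1L, hi - lo + 1L)
        front <- (4 / N) * roll_sum_ramp(ax, starts, 1L, lo - 1L)
        backw <- if (hi + 1L > N) rep(0, K) else {
          # sum (N - i) * v over i in [hi+1, N]
          sums <- roll_sum(ax, starts + hi, N - hi)
          ramp <- roll_sum_ramp(ax, starts, hi + 1L, N)
          (4 / N) * (N * sums - ramp)
        }
        (inner + front + backw) / N
      },
      SSI = s_sq,
      VAR = s_sq / (N - 1),
      RMS = sqrt(s_sq / N),
      WL = s_wl,
      LOG = {
        axc <- ax
        if (any(axc < LOG_FLOOR)) {
          warning("LOG feature: |x| clamped at ", LOG_FLOOR, call. = FALSE)
          axc <- pmax(axc, LOG_FLOOR)
        }
        exp(roll_sum(log(axc), starts, N) / N)
      },
      ZC = roll_sum(as.numeric(x[-n] * x[-1] < 0 & ad >= eps),
                    starts, N - 1L),
      SSC = {
        if (n < 3) rep(0, K) else {
          xm <- x[2:(n - 1)]
          ind <- as.numeric((xm - x[1:(n - 2)]) * (xm - x[3:n]) > 0 &
                              pmax(abs(xm - x[1:(n - 2)]),
                                   abs(xm - x[3:n])) >= eps)
          roll_sum(ind, starts, N - 2L)
        }
      },
      WAMP = roll_sum(as.numeric(ad >= eps), starts, N - 1L),
      AAC = s_wl / N,
      DASDV = sqrt(roll_sum(d^2, starts, N - 1L) / (N - 1))
    )
  }
  list(values = out, starts = starts)
}

#' Sliding-window feature time series for every channel
#'
#' Computes the requested time-domain features over right-aligned sliding
#' windows (timestamp = window end, so feature samples are causal) for each
#' EMG channel of a recording.
#'
#' @param rec an [emg_recording] (preprocessed EMG expected).
#' @param spec a [window_spec].
#' @param names features to compute (default [default_feature_set()]).
#' @param eps threshold for ZC/SSC/WAMP; `NULL` (default) uses 0.01 x the
#'   channel RMS (the protocol is rest-dominated, so channel RMS tracks the
#'   rest-phase RMS).
#' @return named list (per channel) of `feature_series` objects: lists with
#'   `channel`, `feature_names`, `values` (steps x features matrix),
#'   `times` (window-end timestamps, s), `window` (the spec).
#' @export
feature_matrix <- function(rec, spec = window_spec(),
                           names = default_feature_set(), eps = NULL) {
  stopifnot(inherits(rec, "emg_recording"), inherits(spec, "window_spec"))
  fs <- rec$sample_rate
  N <- spec$length_ms * fs / 1000
  step <- spec$step_ms * fs / 1000
  if (abs(N - round(N)) > 1e-9 || abs(step - round(step)) > 1e-9)
    stop("window length and step must be whole sample counts at ",
         fs, " Hz")
  N <- as.integer(round(N)); step <- as.integer(round(step))
  bad <- setdiff(names, emg_features())
  if (length(bad))
    stop("unknown feature(s): ", paste(bad, collapse = ", "))
  out <- list()
  for (ch in rec$channel_names) {
    x <- rec$emg[, ch]
    if (length(x) < N) {
      warning("channel ", ch, ": recording shorter than one window",
              call. = FALSE)
      out[[ch]] <- structure(
        list(channel = ch, feature_names = names,
             values = matrix(numeric(0), 0, length(names),
                             dimnames = list(NULL, names)),
             times = numeric(0), window = spec),
        class = "feature_series")
      next
    }
    e <- if (is.null(eps)) 0.01 * sqrt(mean(x^2)) else eps
    fw <- feature_windows(x, N, step, e, names)
    out[[ch]] <- structure(
      list(channel = ch, feature_names = names, values = fw$values,
           times = rec$time_s[fw$starts + N - 1L], window = spec,
           eps = e),
      class = "feature_series")
  }
  out
}

#' @export
print.feature_series <- function(x, ...) {
  cat("feature_series:", x$channel, "-", nrow(x$values), "steps x",
      length(x$feature_names), "features (",
      paste(x$feature_names, collapse = ", "), ")\n")
  invisible(x)
}
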