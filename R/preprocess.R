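#' Zero-phase filtering with edge padding and steady-state initial conditions
#'
#' Forward-backward application of an IIR filter. The input is extended at
#' both ends by odd reflection (length `3 * filter order`) and each pass is
#' initialised at the steady state of a step of the boundary amplitude, so
#' constant inputs map through a high-pass filter to (numerically) zero and
#' edge transients do not leak into the retained samples.
#'
#' @param b,a filter numerator/denominator coefficients (`a[1]` must be
#'   non-zero; coefficients are normalised internally).
#' @param x numeric vector to filter.
#' @return filtered vector, same length as `x`.
#' @keywords internal
filtfilt_pad <- function(b, a, x) {
  b <- as.numeric(b); a <- as.numeric(a)
  b <- b / a[1]; a <- a / a[1]
  nfilt <- max(length(a), length(b))
  length(a) <- nfilt; length(b) <- nfilt
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  # pad long enough for the slowest pole's transient to die out (~1e-3)
  nfact <- 3L * (nfilt - 1L)
  rmax <- suppressWarnings(max(Mod(polyroot(rev(a)))))
  if (is.finite(rmax) && rmax < 1 && rmax > 0)
    nfact <- max(nfact, ceiling(-7 / log(rmax)))
  n <- length(x)
  if (n <= 3L * (nfilt - 1L))
    stop("series too short for zero-phase filtering: need more than ",
         3L * (nfilt - 1L), " samples, got ", n)
  nfact <- min(nfact, n - 1L)
  # steady-state state vector for unit step input (Gustafsson-style init)
  ns <- nfilt - 1L
  A <- diag(1, ns) - cbind(-a[2:nfilt],
                           rbind(diag(1, ns - 1L), rep(0, ns - 1L)))
  zi <- solve(A, b[2:nfilt] - b[1] * a[2:nfilt])
  ext <- c(2 * x[1] - x[(nfact + 1L):2],
           x,
           2 * x[n] - x[(n - 1L):(n - nfact)])
  y <- .filter_df2t(b, a, ext, zi * ext[1])
  y <- rev(.filter_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1L):(nfact + n)]
}

#' Design a 50 Hz-style IIR notch biquad
#'
#' Standard constrained biquad (cookbook form) with centre frequency `f0`
#' and quality factor `Q` (bandwidth `f0/Q`).
#'
#' @param f0 notch centre frequency, Hz.
#' @param sample_rate sampling rate, Hz.
#' @param Q quality factor (default 30).
#' @return list with components `b` and `a`.
#' @keywords internal
notch_design <- function(f0, sample_rate, Q = 30) {
  w0 <- 2 * pi * f0 / sample_rate
  al <- sin(w0) / (2 * Q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + al),
       a = c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al)))
}

#' Preprocess a raw EMG channel
#'
#' Offline conditioning of one sEMG channel: a 4th-order Butterworth
#' high-pass at `highpass` Hz removes motion artefact and offset drift, then
#' an IIR notch at `notch` Hz removes residual powerline interference. Both
#' filters are applied zero-phase (forward-backward) by default so the group
#' delay does not bias downstream onset-latency estimates; set
#' `causal = TRUE` to emulate single-pass online filtering.
#'
#' @param x numeric vector, raw EMG samples (volts).
#' @param sample_rate sampling rate, Hz (> 100).
#' @param highpass high-pass cutoff, Hz (default 10).
#' @param notch notch centre frequency, Hz (default 50); `NA` disables.
#' @param Q notch quality factor (default 30).
#' @param causal logical; single forward pass instead of zero-phase.
#' @return filtered vector, same length as `x`.
#' @examples
#' x <- sin(2 * pi * 50 * seq(0, 1, by = 1e-3)) + 0.3
#' y <- preprocess_emg(x, 1000)   # DC and 50 Hz both suppressed
#' @export
preprocess_emg <- function(x, sample_rate, highpass = 10, notch = 50,
                           Q = 30, causal = FALSE) {
  if (!is.numeric(x)) stop("x must be numeric")
  if (sample_rate <= 100) stop("sample_rate must exceed 100 Hz")
  if (length(x) <= 40)
    stop("series too short to filter (need > 10 x filter order samples)")
  hp <- signal::butter(4, highpass / (sample_rate / 2), type = "high")
  apply_one <- function(b, a, x) {
    if (causal) {
      # steady-state init at x[1] so a constant maps to its filtered value
      nfilt <- max(length(a), length(b))
      ns <- nfilt - 1L
      A <- diag(1, ns) - cbind(-a[2:nfilt],
                               rbind(diag(1, ns - 1L), rep(0, ns - 1L)))
      zi <- solve(A, b[2:nfilt] - b[1] * a[2:nfilt])
      .filter_df2t(b, a, x, zi * x[1])
    } else {
      filtfilt_pad(b, a, x)
    }
  }
  y <- apply_one(hp$b, hp$a, x)
  if (!is.na(notch) && notch > 0) {
    nf <- notch_design(notch, sample_rate, Q)
    y <- apply_one(nf$b, nf$a, y)
  }
  y
}
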