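#' Two-component Gaussian mixture parameters
#'
#' Parameter set of the scalar rest/movement mixture. The labelling
#' convention `mu_rest <= mu_mov` is enforced (components are swapped if
#' supplied the other way round).
#'
#' @param w_rest,w_mov mixture weights (sum to 1, both in (0, 1)).
#' @param mu_rest,mu_mov component means (feature units).
#' @param var_rest,var_mov component variances (> 0).
#' @return object of class `gmm_params` (named list of the six parameters).
#' @export
gmm_params <- function(w_rest, w_mov, mu_rest, mu_mov, var_rest, var_mov) {
  if (abs(w_rest + w_mov - 1) > 1e-9) stop("weights must sum to 1")
  if (w_rest <= 0 || w_rest >= 1) stop("weights must lie in (0, 1)")
  if (var_rest <= 0 || var_mov <= 0) stop("variances must be positive")
  if (mu_rest > mu_mov) {  # relabel: rest is the low-mean component
    tmp <- list(w_rest = w_mov, w_mov = w_rest, mu_rest = mu_mov,
                mu_mov = mu_rest, var_rest = var_mov, var_mov = var_rest)
  } else {
    tmp <- list(w_rest = w_rest, w_mov = w_mov, mu_rest = mu_rest,
                mu_mov = mu_mov, var_rest = var_rest, var_mov = var_mov)
  }
  structure(tmp, class = "gmm_params")
}

as_gmm_params <- function(x) {
  if (inherits(x, "emg_gmm")) return(x$params)
  if (inherits(x, "gmm_params")) return(x)
  if (is.numeric(x) && length(x) == 6)
    return(gmm_params(x[1], x[2], x[3], x[4], x[5], x[6]))
  stop("cannot interpret object as GMM parameters")
}

par_vec <- function(p) unlist(p[c("w_rest", "w_mov", "mu_rest", "mu_mov",
                                  "var_rest", "var_mov")], use.names = FALSE)

mix_loglik <- function(x, p) {
  lr <- log(p$w_rest) + dnorm(x, p$mu_rest, sqrt(p$var_rest), log = TRUE)
  lm <- log(p$w_mov) + dnorm(x, p$mu_mov, sqrt(p$var_mov), log = TRUE)
  mx <- pmax(lr, lm)
  sum(mx + log(exp(lr - mx) + exp(lm - mx)))
}

#' Fit the rest/movement Gaussian mixture by expectation-maximization
#'
#' Fits a two-component scalar Gaussian mixture to (unlabelled) feature
#' samples. The low-mean component models the rest phase and the high-mean
#' component the movement phase; together with [optimal_threshold()] the fit
#' yields the rest/movement decision boundary, and it seeds the sequential
#' adaptation of [classify_stream()].
#'
#' EM is initialised by splitting the sample at its median and iterated
#' until the largest absolute change over all six parameters falls below
#' `tol`, or `max_iter` iterations.
#'
#' @param x numeric vector of feature samples (training window).
#' @param tol convergence tolerance on the parameter change (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param n_floor minimum admissible training size (default 50).
#' @return object of class `emg_gmm`: list with `params` ([gmm_params]),
#'   `theta` (decision threshold), `n_iter`, `converged`, `logLik`, `n`,
#'   `flags` (variance-floor events), and the data as `x`.
#' @seealso [optimal_threshold()], [classify_stream()], [adaptive_state()]
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 1, 0.5), rnorm(200, 5, 1))
#' fit <- emg_gmm(x)
#' coef(fit)
#' @export
emg_gmm <- function(x, tol = 1e-6, max_iter = 500, n_floor = 50) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("training samples must be finite")
  if (length(x) < n_floor)
    stop("need at least ", n_floor, " training samples, got ", length(x))
  sv <- var(x)
  if (sv == 0) stop("degenerate fit: training samples have zero variance")
  vfloor <- 1e-12 * sv
  m <- median(x)
  g1 <- x <= m
  if (all(g1) || !any(g1)) g1 <- seq_along(x) <= length(x) / 2
  mu <- c(mean(x[g1]), mean(x[!g1]))
  v <- pmax(c(var(x[g1]), var(x[!g1])), vfloor)
  v[is.na(v)] <- vfloor
  w <- c(0.5, 0.5)
  floored <- FALSE
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    l1 <- log(w[1]) + dnorm(x, mu[1], sqrt(v[1]), log = TRUE)
    l2 <- log(w[2]) + dnorm(x, mu[2], sqrt(v[2]), log = TRUE)
    mx <- pmax(l1, l2)
    r1 <- exp(l1 - mx); r2 <- exp(l2 - mx)
    s <- r1 + r2
    r1 <- r1 / s
    n1 <- sum(r1); n2 <- length(x) - n1
    new_w <- c(n1, n2) / length(x)
    new_mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    new_v <- c(sum(r1 * (x - new_mu[1])^2) / n1,
               sum((1 - r1) * (x - new_mu[2])^2) / n2)
    if (any(new_v < vfloor)) {
      new_v <- pmax(new_v, vfloor)
      floored <- TRUE
    }
    delta <- max(abs(c(new_w - w, new_mu - mu, new_v - v)))
    w <- new_w; mu <- new_mu; v <- new_v
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  p <- gmm_params(w[1], w[2], mu[1], mu[2], v[1], v[2])
  th <- optimal_threshold(p)
  structure(list(params = p, theta = as.numeric(th),
                 theta_flags = attributes(th), n_iter = it,
                 converged = converged, logLik = mix_loglik(x, p),
                 n = length(x), flags = list(var_floored = floored),
                 x = x, call = match.call()),
            class = "emg_gmm")
}

#' Optimal rest/movement decision threshold of a fitted mixture
#'
#' Solves `w_rest N(theta; mu_rest, var_rest) = w_mov N(theta; mu_mov,
#' var_mov)` — the minimum-classification-error boundary of the
#' two-component mixture. With unequal variances the log-density equation is
#' quadratic; the root lying between the means is returned when one exists,
#' otherwise the root nearest the inter-mean interval (flagged via the
#' `in_interval` attribute). Equal variances are solved in closed form.
#'
#' @param params a [gmm_params], `emg_gmm` fit, or numeric vector of the six
#'   parameters.
#' @return threshold (numeric scalar) with attributes `in_interval` and
#'   `degenerate`.
#' @examples
#' optimal_threshold(gmm_params(0.5, 0.5, 0, 1, 1, 1))  # 0.5
#' @export
optimal_threshold <- function(params) {
  p <- as_gmm_params(params)
  r <- .solve_theta_cpp(p$w_rest, p$mu_rest, p$var_rest,
                        p$w_mov, p$mu_mov, p$var_mov)
  structure(r[1], in_interval = r[2] == 1, degenerate = r[3] == 1)
}

#' Component responsibilities (posterior membership probabilities)
#'
#' `p(i | x) = w_i N(x; mu_i, var_i) / sum_j w_j N(x; mu_j, var_j)` for
#' `i` in rest, movement. Computed in log space; if both densities
#' underflow, the sample is assigned to the nearer-mean component.
#'
#' @param x numeric vector of feature values.
#' @param params a [gmm_params] (or coercible).
#' @return matrix with columns `p_rest`, `p_mov` (rows sum to 1).
#' @export
responsibilities <- function(x, params) {
  p <- as_gmm_params(params)
  lr <- log(p$w_rest) + dnorm(x, p$mu_rest, sqrt(p$var_rest), log = TRUE)
  lm <- log(p$w_mov) + dnorm(x, p$mu_mov, sqrt(p$var_mov), log = TRUE)
  mx <- pmax(lr, lm)
  er <- exp(lr - mx); em <- exp(lm - mx)
  pr <- er / (er + em)
  bad <- !is.finite(pr)
  if (any(bad))
    pr[bad] <- as.numeric(abs(x[bad] - p$mu_rest) <= abs(x[bad] - p$mu_mov))
  cbind(p_rest = pr, p_mov = 1 - pr)
}

#' Adaptive classifier state for sequential threshold tracking
#'
#' Bundles the current mixture parameters with the forgetting factor
#' `alpha = (L - 1)/L` and the current decision threshold. `L` is the
#' effective memory length in update steps (10 ms each at the default
#' update rate), so old samples are discounted with weight `alpha^t`.
#'
#' @param params initial [gmm_params] (typically from [emg_gmm()]).
#' @param L effective memory length, steps (default 1000, i.e. 10 s).
#' @param var_floor absolute variance floor during adaptation; default
#'   `1e-12 * max(var_rest, var_mov)`.
#' @return object of class `adaptive_state`.
#' @export
adaptive_state <- function(params, L = 1000, var_floor = NULL) {
  p <- as_gmm_params(params)
  if (L < 1) stop("L must be >= 1")
  structure(list(params = p, alpha = (L - 1) / L, L = L,
                 theta = as.numeric(optimal_threshold(p)),
                 var_floor = var_floor %||% (1e-12 * max(p$var_rest,
                                                         p$var_mov)),
                 step_index = 0L),
            class = "adaptive_state")
}

#' One sequential update of the adaptive mixture
#'
#' Folds a new observation into the mixture with exponential forgetting:
#' weights are updated as `w_i <- alpha w_i + (1 - alpha) p(i | x)`, means
#' and variances by the matching responsibility-weighted recursions (the
#' variance update uses the already-updated mean), and the decision
#' threshold is recomputed from the updated parameters. With `alpha = 1`
#' (infinite memory) the update is a no-op.
#'
#' @param state an [adaptive_state].
#' @param x_new the new feature observation (scalar).
#' @return the updated `adaptive_state`.
#' @export
sequential_update <- function(state, x_new) {
  stopifnot(inherits(state, "adaptive_state"))
  a <- state$alpha
  p <- state$params
  if (a < 1) {
    r <- responsibilities(x_new, p)
    pr <- unname(r[1, 1]); pm <- unname(r[1, 2])
    w_r <- a * p$w_rest + (1 - a) * pr
    w_m <- a * p$w_mov + (1 - a) * pm
    s <- w_r + w_m
    w_r <- w_r / s
    w_m <- 1 - w_r  # weight sum exactly 1 in floating point
    mu_r <- (a * p$w_rest * p$mu_rest + (1 - a) * pr * x_new) / w_r
    mu_m <- (a * p$w_mov * p$mu_mov + (1 - a) * pm * x_new) / w_m
    v_r <- (a * p$w_rest * p$var_rest +
              (1 - a) * pr * (x_new - mu_r)^2) / w_r
    v_m <- (a * p$w_mov * p$var_mov +
              (1 - a) * pm * (x_new - mu_m)^2) / w_m
    if (v_r < state$var_floor) v_r <- state$var_floor
    if (v_m < state$var_floor) v_m <- state$var_floor
    state$params <- structure(list(w_rest = w_r, w_mov = w_m,
                                   mu_rest = mu_r, mu_mov = mu_m,
                                   var_rest = v_r, var_mov = v_m),
                              class = "gmm_params")
    state$theta <- as.numeric(optimal_threshold(state$params))
  }
  state$step_index <- state$step_index + 1L
  state
}

#' Stream classification with sequentially adapted threshold
#'
#' Classifies a feature time series step by step: each sample is compared
#' against the current threshold (at/above = movement), then the mixture is
#' updated with that sample (exponential forgetting, see
#' [sequential_update()]) and the threshold recomputed. Deterministic.
#'
#' @param x numeric vector, one feature's time series at the update rate.
#' @param init initial parameters ([emg_gmm] fit or [gmm_params]).
#' @param L effective memory length, steps (default 1000).
#' @param adapt logical; `FALSE` freezes the initial threshold (ablation).
#' @param var_floor variance floor during adaptation (see
#'   [adaptive_state()]).
#' @return list with `labels` (integer 0 = rest / 1 = movement), `theta`
#'   (per-step threshold trace), `params` (final [gmm_params]),
#'   `n_floored`, `n_theta_outside`.
#' @export
classify_stream <- function(x, init, L = 1000, adapt = TRUE,
                            var_floor = NULL) {
  p <- as_gmm_params(init)
  vf <- var_floor %||% (1e-12 * max(p$var_rest, p$var_mov))
  alpha <- (L - 1) / L
  r <- .classify_stream_cpp(as.numeric(x), par_vec(p), alpha,
                            isTRUE(adapt), vf)
  r$params <- structure(as.list(stats::setNames(
    r$params, c("w_rest", "w_mov", "mu_rest", "mu_mov",
                "var_rest", "var_mov"))), class = "gmm_params")
  r
}

# ---- S3 methods for the fitted model ----------------------------------

#' @export
print.gmm_params <- function(x, ...) {
  cat(sprintf("gmm_params: w = (%.4f, %.4f), mu = (%.4g, %.4g), var = (%.4g, %.4g)\n",
              x$w_rest, x$w_mov, x$mu_rest, x$mu_mov, x$var_rest, x$var_mov))
  invisible(x)
}

#' @export
print.emg_gmm <- function(x, ...) {
  cat("Two-component rest/movement Gaussian mixture (EM fit)\n")
  cat(sprintf("  n = %d, %s in %d iterations, logLik = %.3f\n", x$n,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              x$logLik))
  print(x$params)
  cat(sprintf("  decision threshold theta = %.6g\n", x$theta))
  invisible(x)
}

#' @export
coef.emg_gmm <- function(object, ...) {
  stats::setNames(par_vec(object$params),
                  c("w_rest", "w_mov", "mu_rest", "mu_mov",
                    "var_rest", "var_mov"))
}

#' @export
logLik.emg_gmm <- function(object, ...) {
  structure(object$logLik, df = 5, nobs = object$n, class = "logLik")
}

#' @export
summary.emg_gmm <- function(object, ...) {
  p <- object$params
  sep <- abs(p$mu_mov - p$mu_rest) /
    sqrt(0.5 * (p$var_rest + p$var_mov))
  out <- list(fit = object, separation = sep,
              p_overlap_rest = 1 - stats::pnorm(
                (object$theta - p$mu_rest) / sqrt(p$var_rest)))
  class(out) <- "summary.emg_gmm"
  out
}

#' @export
print.summary.emg_gmm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  component separation (d') = %.3f\n", x$separation))
  cat(sprintf("  rest-tail mass beyond theta = %.4g\n", x$p_overlap_rest))
  invisible(x)
}

#' Classify new feature values with a fitted mixture
#'
#' @param object an `emg_gmm` fit.
#' @param newdata numeric vector of feature values (defaults to the
#'   training data).
#' @param type `"label"` (0 = rest, 1 = movement, fixed threshold),
#'   `"responsibility"` (posterior matrix) or `"density"` (mixture pdf).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.emg_gmm <- function(object, newdata = NULL,
                            type = c("label", "responsibility", "density"),
                            ...) {
  type <- match.arg(type)
  x <- newdata %||% object$x
  p <- object$params
  switch(type,
    label = as.integer(x >= object$theta),
    responsibility = responsibilities(x, p),
    density = p$w_rest * dnorm(x, p$mu_rest, sqrt(p$var_rest)) +
      p$w_mov * dnorm(x, p$mu_mov, sqrt(p$var_mov)))
}

#' Simulate from a fitted rest/movement mixture
#'
#' @param object an `emg_gmm` fit.
#' @param nsim number of samples.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return numeric vector of `nsim` draws from the mixture.
#' @export
simulate.emg_gmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  mov <- runif(nsim) < p$w_mov
  rnorm(nsim,
        ifelse(mov, p$mu_mov, p$mu_rest),
        sqrt(ifelse(mov, p$var_mov, p$var_rest)))
}

#' @export
plot.emg_gmm <- function(x, breaks = 50, ...) {
  p <- x$params
  h <- graphics::hist(x$x, breaks = breaks, freq = FALSE,
                      main = "rest/movement mixture fit",
                      xlab = "feature value", border = "grey70", ...)
  xs <- seq(min(h$breaks), max(h$breaks), length.out = 400)
  graphics::lines(xs, p$w_rest * dnorm(xs, p$mu_rest, sqrt(p$var_rest)),
                  col = "steelblue", lwd = 2)
  graphics::lines(xs, p$w_mov * dnorm(xs, p$mu_mov, sqrt(p$var_mov)),
                  col = "firebrick", lwd = 2)
  graphics::abline(v = x$theta, lty = 2)
  invisible(x)
}

# ---- flat key-value model serialization --------------------------------

#' Write fitted mixture models to a flat text file
#'
#' One line per (muscle, feature) pair: tab-separated key-value records of
#' the six mixture parameters, preceded by `#` metadata lines.
#'
#' @param models nested list `models[[muscle]][[feature]]` of `emg_gmm` or
#'   [gmm_params] objects.
#' @param path output path.
#' @param meta named list of metadata strings (training session, window).
#' @return `path`, invisibly.
#' @export
write_gmm_models <- function(models, path, meta = list()) {
  lines <- vapply(names(meta), function(k)
    paste0("# ", k, ": ", meta[[k]]), character(1))
  lines <- c(lines, paste("muscle", "feature", "w_rest", "w_mov", "mu_rest",
                          "mu_mov", "var_rest", "var_mov", sep = "\t"))
  for (m in names(models)) for (f in names(models[[m]])) {
    p <- as_gmm_params(models[[m]][[f]])
    lines <- c(lines, paste(m, f,
                            paste(format(par_vec(p), digits = 17),
                                  collapse = "\t"), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read fitted mixture models from a flat text file
#'
#' @param path file written by [write_gmm_models()].
#' @return nested list `models[[muscle]][[feature]]` of [gmm_params].
#' @export
read_gmm_models <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  dt <- utils::read.delim(text = paste(ln, collapse = "\n"),
                          stringsAsFactors = FALSE)
  models <- list()
  for (i in seq_len(nrow(dt))) {
    r <- dt[i, ]
    models[[r$muscle]][[r$feature]] <-
      gmm_params(r$w_rest, r$w_mov, r$mu_rest, r$mu_mov,
                 r$var_rest, r$var_mov)
  }
  models
}
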