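#' Equipopulated binning of a feature sequence
#'
#' Assigns each value to one of `n_bins` rank-based equipopulated bins
#' (deterministic; invariant under strictly monotone transforms of the
#' values). Quantile edges are returned as provenance.
#'
#' @param values numeric vector.
#' @param n_bins number of bins (>= 2).
#' @return list with `bins` (integer in `[0, n_bins)`) and `edges`
#'   (`n_bins + 1` quantile edges).
#' @export
bin_feature <- function(values, n_bins = 4) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (length(unique(values)) < n_bins)
    stop("too few distinct values for ", n_bins,
         " bins; use fewer bins")
  n <- length(values)
  r <- rank(values, ties.method = "first")
  bins <- as.integer(floor((r - 1) * n_bins / n))
  edges <- unname(quantile(values, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 1))
  list(bins = bins, edges = edges)
}

#' Binned response container for information estimates
#'
#' Pools one or more feature channels (already reduced to per-step values)
#' with the per-step phase label into the discretized form used by the
#' mutual-information estimators.
#'
#' @param values numeric matrix (steps x channels) of feature values, or a
#'   vector for a single channel.
#' @param labels per-step phase labels (`0` rest / `1` movement, or any
#'   discrete codes); steps with `NA` labels are dropped.
#' @param n_bins bins per channel (default 4).
#' @return object of class `binned_response`: `labels`, `bins` (matrix of
#'   integer bin indices), `n_bins`, `edges` (per-channel list).
#' @export
binned_response <- function(values, labels, n_bins = 4) {
  values <- as.matrix(values)
  if (nrow(values) != length(labels))
    stop("labels and values must share length")
  keep <- !is.na(labels) & complete.cases(values)
  values <- values[keep, , drop = FALSE]
  labels <- labels[keep]
  bins <- matrix(0L, nrow(values), ncol(values),
                 dimnames = list(NULL, colnames(values)))
  edges <- list()
  for (j in seq_len(ncol(values))) {
    b <- bin_feature(values[, j], n_bins)
    bins[, j] <- b$bins
    edges[[j]] <- b$edges
  }
  structure(list(labels = labels, bins = bins, n_bins = n_bins,
                 edges = edges),
            class = "binned_response")
}

joint_state <- function(bins, channels, n_bins) {
  b <- bins[, channels, drop = FALSE]
  f <- rep(0, nrow(b))
  for (j in seq_along(channels)) f <- f * n_bins + b[, j]
  f
}

plugin_mi <- function(r, f) {
  tab <- table(r, f)
  n <- sum(tab)
  pj <- tab / n
  pr <- rowSums(pj); pf <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / (pr[row(pj)[nz]] * pf[col(pj)[nz]])))
}

pt_bias <- function(r, f) {
  # Panzeri-Treves-style first-order bias of the plug-in estimate,
  # with naive counting of occupied response bins
  tab <- table(r, f)
  n <- sum(tab)
  R_r <- rowSums(tab > 0)
  R_tot <- sum(colSums(tab) > 0)
  (sum(R_r - 1) - (R_tot - 1)) / (2 * n * log(2))
}

#' Mutual information between phase and binned features
#'
#' Plug-in estimate `I(R; F)` (bits) over the joint binned states of the
#' selected channels, optionally debiased by a Panzeri-Treves-style
#' correction (subtracting the first-order sampling bias estimated from the
#' occupied-bin counts). By default the correction is applied for fewer
#' than 10,000 samples.
#'
#' @param binned a [binned_response].
#' @param channels channel indices or names (default: all).
#' @param bias_correct logical; `NULL` = auto (`n < 10000`).
#' @param state_cap maximum joint state count (default 256).
#' @return information in bits (attribute `bias` holds the subtracted
#'   term).
#' @export
mutual_info <- function(binned, channels = NULL, bias_correct = NULL,
                        state_cap = 256) {
  stopifnot(inherits(binned, "binned_response"))
  channels <- channels %||% seq_len(ncol(binned$bins))
  if (!length(channels)) stop("channel subset must be non-empty")
  if (binned$n_bins^length(channels) > state_cap)
    stop("joint state space exceeds cap (", state_cap,
         "); use fewer channels or bins")
  f <- joint_state(binned$bins, channels, binned$n_bins)
  r <- binned$labels
  i <- plugin_mi(r, f)
  bc <- bias_correct %||% (length(r) < 10000)
  b <- if (bc) pt_bias(r, f) else 0
  structure(i - b, bias = b)
}

#' Information breakdown into linear, redundancy and synergy terms
#'
#' Decomposes the joint mutual information between the phase `R` and a set
#' of feature channels `F` as `I(R;F) = I_lin + I_sig_sim + I_cor_ind +
#' I_cor_dep`. `I_lin` sums the single-channel informations; `I_sig_sim`
#' (<= 0) measures redundancy from similarity of the phase-conditional
#' response distributions (via the conditionally-independent surrogate);
#' the two correlation terms quantify synergy from phase-independent and
#' phase-dependent correlations. The four terms sum to the plug-in
#' `I_total` exactly by construction.
#'
#' @param binned a [binned_response].
#' @param channels channel indices or names (default: all).
#' @return object of class `info_breakdown` with fields `I_total`,
#'   `I_lin`, `I_sig_sim`, `I_cor_ind`, `I_cor_dep` (bits).
#' @export
info_breakdown <- function(binned, channels = NULL) {
  stopifnot(inherits(binned, "binned_response"))
  channels <- channels %||% seq_len(ncol(binned$bins))
  nb <- binned$n_bins
  r <- binned$labels
  n <- length(r)
  if (length(channels) == 1) {
    itot <- plugin_mi(r, binned$bins[, channels])
    out <- list(I_total = itot, I_lin = itot, I_sig_sim = 0,
                I_cor_ind = 0, I_cor_dep = 0)
    return(structure(out, class = "info_breakdown"))
  }
  C <- length(channels)
  rs <- sort(unique(r))
  pr <- as.numeric(table(factor(r, levels = rs))) / n
  # per-channel conditionals P(f_c | r): list of nb x S matrices
  cond <- lapply(channels, function(ch) {
    t(vapply(rs, function(rv) {
      tabulate(binned$bins[r == rv, ch] + 1L, nbins = nb) / sum(r == rv)
    }, numeric(nb)))  # S x nb
  })
  # product-space conditionally independent surrogate over nb^C states
  grid <- as.matrix(expand.grid(rep(list(0:(nb - 1L)), C)))
  p_ind_cond <- matrix(1, nrow(grid), length(rs))  # states x S
  for (j in seq_len(C))
    p_ind_cond <- p_ind_cond * t(cond[[j]])[grid[, j] + 1L, , drop = FALSE]
  p_ind <- as.numeric(p_ind_cond %*% pr)
  # I_ind: MI of the surrogate
  iind <- 0
  for (s in seq_along(rs)) {
    nz <- p_ind_cond[, s] > 0
    iind <- iind + pr[s] * sum(p_ind_cond[nz, s] *
                                 log2(p_ind_cond[nz, s] / p_ind[nz]))
  }
  # observed joint conditionals over the same enumerated states
  f_obs <- joint_state(binned$bins, channels, nb)
  state_id <- rep(0, nrow(grid))
  for (j in seq_len(C)) state_id <- state_id * nb + grid[, j]
  # align: joint_state folds channels left-to-right the same way
  p_cond <- vapply(seq_along(rs), function(s) {
    cnt <- table(factor(f_obs[r == rs[s]], levels = state_id))
    as.numeric(cnt) / sum(r == rs[s])
  }, numeric(nrow(grid)))  # states x S
  p_f <- as.numeric(p_cond %*% pr)
  itot <- 0
  for (s in seq_along(rs)) {
    nz <- p_cond[, s] > 0
    itot <- itot + pr[s] * sum(p_cond[nz, s] *
                                 log2(p_cond[nz, s] / p_f[nz]))
  }
  ilin <- sum(vapply(channels, function(ch)
    plugin_mi(r, binned$bins[, ch]), numeric(1)))
  isig <- iind - ilin
  icd <- 0
  for (s in seq_along(rs)) {
    nz <- p_cond[, s] > 0
    icd <- icd + pr[s] * sum(p_cond[nz, s] *
                               log2(p_cond[nz, s] * p_ind[nz] /
                                      (p_ind_cond[nz, s] * p_f[nz])))
  }
  ici <- itot - iind - icd
  structure(list(I_total = itot, I_lin = ilin, I_sig_sim = isig,
                 I_cor_ind = ici, I_cor_dep = icd),
            class = "info_breakdown")
}

#' @export
print.info_breakdown <- function(x, ...) {
  cat(sprintf(
    "info_breakdown (bits): total %.4f = lin %.4f + sig-sim %.4f + cor-ind %.4f + cor-dep %.4f\n",
    x$I_total, x$I_lin, x$I_sig_sim, x$I_cor_ind, x$I_cor_dep))
  invisible(x)
}

#' Screen features against a white-noise information baseline
#'
#' Kruskal-Wallis test across all feature groups plus the white-noise
#' baseline, followed by per-feature one-sided rank-sum comparisons against
#' the baseline. Features carrying significantly more information than
#' noise (default p < 0.001) are retained.
#'
#' @param info numeric matrix, replicates (subject/session/muscle units) in
#'   rows, features in columns; entries are information in bits.
#' @param noise_info numeric vector: the same information estimate computed
#'   on white Gaussian noise run through the identical pipeline.
#' @param alpha significance level (default 0.001).
#' @return list with `retained` (feature names), `kw_p`, `p_values`.
#' @export
screen_features <- function(info, noise_info, alpha = 0.001) {
  info <- as.matrix(info)
  if (ncol(info) < 2) stop("need at least 2 features to screen")
  if (nrow(info) < 3 || length(noise_info) < 3)
    stop("need at least 3 replicates per group")
  groups <- c(lapply(seq_len(ncol(info)), function(j) info[, j]),
              list(noise = noise_info))
  names(groups) <- c(colnames(info), "noise")
  kw <- kruskal.test(groups)
  pv <- vapply(colnames(info), function(f)
    suppressWarnings(wilcox.test(info[, f], noise_info,
                                 alternative = "greater")$p.value),
    numeric(1))
  list(retained = colnames(info)[pv < alpha], kw_p = kw$p.value,
       p_values = pv)
}

# minimal union-find for connected components
uf_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(a) { while (parent[[a]] != a) a <- parent[[a]]; a }
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    ra <- find(edges[i, 1]); rb <- find(edges[i, 2])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, character(1))
}

#' Select the minimally redundant, synergistic feature set
#'
#' Builds a graph on the retained features with an edge wherever the
#' pairwise correlation (synergy) term `I_cor_ind + I_cor_dep` is negative
#' (non-synergistic pair), and keeps from each connected component the
#' single feature with the highest mean single-feature information.
#'
#' @param retained character vector of screened feature names.
#' @param corr_term symmetric numeric matrix (features x features) of
#'   pairwise `I_cor_ind + I_cor_dep` values, bits.
#' @param single_info named numeric vector of mean single-feature
#'   information, bits.
#' @return character vector: the selected feature set (in canonical
#'   registry order).
#' @export
select_feature_set <- function(retained, corr_term, single_info) {
  if (!length(retained)) stop("retained feature list is empty")
  retained <- intersect(emg_features(), retained)  # canonical order
  pairs <- utils::combn(retained, 2)
  neg <- apply(pairs, 2, function(p) corr_term[p[1], p[2]] < 0)
  edges <- t(pairs[, neg, drop = FALSE])
  comp <- uf_components(retained, edges)
  keep <- vapply(unique(comp), function(cc) {
    members <- retained[comp == cc]
    members[which.max(single_info[members])]
  }, character(1))
  intersect(emg_features(), keep)
}

#' Joint information carried by each muscle's feature set
#'
#' For each muscle, the joint mutual information (bits) between the phase
#' labels and the binned values of the selected features — the information
#' available to that muscle's Type1 detector.
#'
#' @param features named list of `feature_series` (per muscle).
#' @param labels per-step phase labels (0/1, `NA` dropped).
#' @param feature_set features to pool (default [default_feature_set()]).
#' @param n_bins bins per feature (default 4).
#' @param bias_correct passed to [mutual_info()].
#' @return named numeric vector of bits, one per muscle.
#' @export
muscle_information <- function(features, labels,
                               feature_set = default_feature_set(),
                               n_bins = 4, bias_correct = NULL) {
  vapply(names(features), function(m) {
    v <- features[[m]]$values[, feature_set, drop = FALSE]
    br <- binned_response(v, labels, n_bins)
    as.numeric(mutual_info(br, bias_correct = bias_correct))
  }, numeric(1))
}

#' Rank muscles by information content
#'
#' Orders muscles by the joint information their feature set carries about
#' the rest/movement phase and returns the top-P subset for the
#' information-based multi-muscle detector.
#'
#' @param info named numeric vector of per-muscle information (bits), e.g.
#'   from [muscle_information()].
#' @param P subset size (default 3).
#' @return list with `ranking` (muscle names, descending information),
#'   `info` (sorted values) and `top` (first `P` muscles).
#' @export
rank_muscles <- function(info, P = 3) {
  ord <- order(info, decreasing = TRUE)
  ranking <- names(info)[ord]
  list(ranking = ranking, info = info[ord],
       top = ranking[seq_len(min(P, length(ranking)))])
}

#' Compare feature information across window lengths
#'
#' Friedman test across paired information samples at several window
#' lengths, with pairwise paired Wilcoxon signed-rank follow-ups.
#'
#' @param info numeric matrix: paired units in rows, window lengths in
#'   columns (column names e.g. `"100"`, `"300"`, `"500"`).
#' @return list with `friedman` (htest) and `pairwise` (data.frame of
#'   length pairs, V statistics and p-values).
#' @export
compare_window_lengths <- function(info) {
  info <- as.matrix(info)
  if (any(is.na(info))) stop("window-length comparison requires paired",
                             " (complete) observations")
  fr <- friedman.test(info)
  if (is.nan(fr$p.value)) fr$p.value <- 1  # zero spread: no difference
  cmb <- utils::combn(colnames(info), 2)
  pw <- data.frame(a = cmb[1, ], b = cmb[2, ], V = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(cmb))) {
    wt <- suppressWarnings(wilcox.test(info[, cmb[1, i]], info[, cmb[2, i]],
                                       paired = TRUE))
    pw$V[i] <- unname(wt$statistic)
    pw$p[i] <- wt$p.value
  }
  list(friedman = fr, pairwise = pw)
}

#' Per-step phase labels from trial segmentations
#'
#' Maps feature-step timestamps onto the rest (0) / movement (1) phases of
#' the given event; steps outside both phases (including the reaction gap)
#' get `NA` and are excluded from information estimates.
#'
#' @param trials trial segmentations from [segment_trials()] (with
#'   reference onsets where available).
#' @param step_times window-end timestamps, s.
#' @param event `"GoForward"` or `"GoBackward"`.
#' @return integer vector (0/1/`NA`) aligned with `step_times`.
#' @export
phase_labels <- function(trials, step_times, event) {
  lab <- rep(NA_integer_, length(step_times))
  for (tr in trials) {
    if (tr$event != event) next
    lab[step_times >= tr$rest_time[1] & step_times < tr$rest_time[2]] <- 0L
    lab[step_times >= tr$movement_time[1] &
          step_times < tr$movement_time[2]] <- 1L
  }
  lab
}
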