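test_that("rank binning is equipopulated, deterministic, rank-invariant", {
  set.seed(101)
  v <- runif(1000)
  b <- bin_feature(v, 4)
  expect_equal(unname(table(b$bins)), rep(250L, 4), ignore_attr = TRUE)
  expect_identical(b$bins, bin_feature(v, 4)$bins)
  # strictly monotone transform leaves assignments unchanged
  expect_identical(bin_feature(exp(3 * v) + 1, 4)$bins, b$bins)
  expect_error(bin_feature(rep(1, 100), 4), "distinct")
  expect_error(bin_feature(v, 1), "n_bins")
})

test_that("mutual information reproduces canonical values", {
  # feature bin identical to the phase label: exactly 1 bit
  r <- rep(0:1, 500)
  br <- binned_response(r + seq(0, 0.5, length.out = 1000), r, n_bins = 2)
  expect_equal(as.numeric(mutual_info(br, bias_correct = FALSE)), 1,
               tolerance = 1e-9)
  # independent feature: near zero with the bias correction
  set.seed(102)
  n <- 50000
  r2 <- rbinom(n, 1, 0.5)
  br2 <- binned_response(rnorm(n), r2, n_bins = 4)
  expect_lt(abs(as.numeric(mutual_info(br2, bias_correct = TRUE))), 0.01)
  # channel-permutation invariance of the joint estimate
  set.seed(103)
  x <- cbind(a = rnorm(2000, r2[1:2000]), b = rnorm(2000, 2 * r2[1:2000]))
  br3 <- binned_response(x, r2[1:2000])
  expect_equal(as.numeric(mutual_info(br3, c(1, 2))),
               as.numeric(mutual_info(br3, c(2, 1))), tolerance = 1e-12)
  expect_error(mutual_info(br3, integer(0)), "non-empty")
  expect_error(mutual_info(br3, c(1, 2), state_cap = 3), "cap")
})

test_that("breakdown terms sum exactly and behave in limiting cases", {
  set.seed(104)
  n <- 50000
  r <- rbinom(n, 1, 0.5)
  # conditionally independent channels: correlation terms ~ 0
  x <- cbind(rnorm(n, r), rnorm(n, r))
  bd <- info_breakdown(binned_response(x, r))
  expect_lt(abs(bd$I_cor_ind), 0.02)
  expect_lt(abs(bd$I_cor_dep), 0.02)
  expect_equal(bd$I_total,
               bd$I_lin + bd$I_sig_sim + bd$I_cor_ind + bd$I_cor_dep,
               tolerance = 1e-12)
  expect_lte(bd$I_sig_sim, 1e-9)
  # duplicated channel: no information gain, fully redundant
  xd <- cbind(x[, 1], 2 * x[, 1] + 1)
  bdd <- info_breakdown(binned_response(xd, r))
  i1 <- as.numeric(mutual_info(binned_response(x[, 1], r),
                               bias_correct = FALSE))
  expect_lt(abs(bdd$I_total - i1), 0.02)
  expect_lt(bdd$I_sig_sim, 0)
  expect_lte(bdd$I_total, i1 + 1e-9)  # data-processing bound
  # single channel: degenerate breakdown (I, I, 0, 0, 0)
  bd1 <- info_breakdown(binned_response(x[, 1], r))
  expect_equal(bd1$I_lin, bd1$I_total)
  expect_identical(c(bd1$I_sig_sim, bd1$I_cor_ind, bd1$I_cor_dep),
                   c(0, 0, 0))
})

test_that("near-deterministic duplicated coding gives I_sig_sim ~ -I_lin/2", {
  set.seed(105)
  n <- 20000
  r <- rbinom(n, 1, 0.5)
  x1 <- r + rnorm(n, 0, 0.05)   # almost noiseless 1-bit code
  bd <- info_breakdown(binned_response(cbind(x1, x1 + 1), r, n_bins = 2))
  expect_equal(bd$I_sig_sim, -bd$I_lin / 2, tolerance = 0.02)
})

test_that("screening retains exactly the informative features", {
  set.seed(106)
  n_units <- 24
  informative <- c("IAV", "MAV", "MMAV1", "SSI", "VAR", "RMS", "WL", "LOG")
  uninformative <- setdiff(emg_features(), informative)
  info <- cbind(
    matrix(rnorm(n_units * length(informative), 0.5, 0.05), n_units,
           dimnames = list(NULL, informative)),
    matrix(abs(rnorm(n_units * length(uninformative), 0.015, 0.005)),
           n_units, dimnames = list(NULL, uninformative)))
  noise <- abs(rnorm(n_units, 0.015, 0.005))
  scr <- screen_features(info, noise)
  expect_setequal(scr$retained, informative)
  expect_lt(scr$kw_p, 0.001)
  # order invariance
  perm <- sample(ncol(info))
  expect_setequal(screen_features(info[, perm], noise)$retained,
                  informative)
  # all-noise input retains nothing
  null_info <- matrix(abs(rnorm(n_units * 4, 0.015, 0.005)), n_units,
                      dimnames = list(NULL, c("IAV", "SSI", "WL", "LOG")))
  expect_length(screen_features(null_info, noise)$retained, 0)
  expect_error(screen_features(info[1:2, ], noise), "replicates")
})

test_that("redundancy/synergy selection keeps group leaders", {
  retained <- c("IAV", "MAV", "MMAV1", "SSI", "VAR", "RMS", "WL", "LOG")
  corr <- matrix(0.05, 14, 14, dimnames = list(emg_features(),
                                               emg_features()))
  neg <- function(a, b) corr[a, b] <<- corr[b, a] <<- -0.05
  for (p in utils::combn(c("IAV", "MAV", "MMAV1"), 2,
                         simplify = FALSE)) neg(p[1], p[2])
  for (p in utils::combn(c("SSI", "RMS", "VAR"), 2,
                         simplify = FALSE)) neg(p[1], p[2])
  single <- c(IAV = 0.6, MAV = 0.55, MMAV1 = 0.5, SSI = 0.62, VAR = 0.5,
              RMS = 0.58, WL = 0.5, LOG = 0.52)
  sel <- select_feature_set(retained, corr, single)
  expect_identical(sel, c("IAV", "SSI", "WL", "LOG"))
  # order invariance and the no-negative-edges case
  expect_identical(select_feature_set(rev(retained), corr, single), sel)
  expect_setequal(select_feature_set(retained, abs(corr), single),
                  retained)
  expect_error(select_feature_set(character(0), corr, single), "empty")
})

test_that("muscle ranking orders by information and returns top-P", {
  info <- c(Trapezius = 0.3, AnteriorDeltoid = 0.9,
            PosteriorDeltoid = 0.7, Biceps = 0.6, Triceps = 0.2,
            FlexorCarpiUlnaris = 0.05, ExtensorCarpiUlnaris = 0.1)
  rk <- rank_muscles(info, P = 3)
  expect_identical(rk$top, c("AnteriorDeltoid", "PosteriorDeltoid",
                             "Biceps"))
  expect_identical(rank_muscles(info[sample(7)], P = 3)$ranking,
                   rk$ranking)
  expect_length(rank_muscles(info, P = 7)$top, 7)
})

test_that("the generator's most active muscle ranks first", {
  prep <- fast_prepared(1)
  lab <- ground_truth_labels(prep$truth, prep$features[[1]]$times,
                             "GoForward")
  info <- muscle_information(prep$features, lab)
  expect_setequal(rank_muscles(info)$top,
                  c("AnteriorDeltoid", "PosteriorDeltoid", "Biceps"))
})

test_that("window-length comparison flags a degraded condition", {
  set.seed(107)
  base <- rnorm(20, 0.5, 0.02)
  tab <- cbind(`100` = base + rnorm(20, 0, 0.01),
               `300` = base + rnorm(20, 0, 0.01),
               `500` = base - 0.1 + rnorm(20, 0, 0.01))
  res <- compare_window_lengths(tab)
  expect_lt(res$friedman$p.value, 0.05)
  pw <- res$pairwise
  expect_lt(pw$p[pw$a == "100" & pw$b == "500"], 0.05)
  expect_lt(pw$p[pw$a == "300" & pw$b == "500"], 0.05)
  # identical information across lengths: nothing to report
  same <- cbind(`100` = base, `300` = base, `500` = base)
  expect_gt(compare_window_lengths(same)$friedman$p.value, 0.99)
  expect_error(compare_window_lengths(cbind(base, c(NA, base[-1]))),
               "paired")
})
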