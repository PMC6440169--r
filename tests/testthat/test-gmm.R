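test_that("EM recovers a known two-component mixture", {
  set.seed(1234)
  x <- c(rnorm(6000, 1, 0.5), rnorm(4000, 5, 1.0))
  fit <- emg_gmm(x)
  expect_true(fit$converged)
  expect_lt(fit$n_iter, 500)
  p <- coef(fit)
  expect_lt(abs(p["mu_rest"] - 1) / 1, 0.02)
  expect_lt(abs(p["mu_mov"] - 5) / 5, 0.02)
  expect_lt(abs(p["w_rest"] - 0.6), 0.03)
  expect_equal(unname(p["w_rest"] + p["w_mov"]), 1)
})

test_that("EM handles separable and degenerate inputs per contract", {
  xx <- rep(c(0, 10), 60)
  fit <- emg_gmm(xx)
  expect_equal(unname(coef(fit)[c("mu_rest", "mu_mov")]), c(0, 10),
               tolerance = 1e-8)
  expect_equal(unname(coef(fit)["w_rest"]), 0.5, tolerance = 1e-8)
  expect_true(fit$flags$var_floored)
  expect_error(emg_gmm(rep(3, 100)), "zero variance")
  expect_error(emg_gmm(rnorm(10)), "at least 50")
  expect_error(emg_gmm(c(rnorm(99), NA)), "finite")
})

test_that("EM log-likelihood matches an independent reference fit", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(42)
  x <- c(rnorm(3000, 1, 0.5), rnorm(2000, 5, 1.0))
  fit <- emg_gmm(x, tol = 1e-10, max_iter = 5000)
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE,
                control = emControl(tol = c(1e-14, 1e-14),
                                    itmax = c(10000, 10000)))
  expect_lt(abs(fit$logLik - ref$loglik), 1e-6)
})

test_that("optimal threshold solves the density-equality equation", {
  # symmetric equal-variance case: exact midpoint
  th <- optimal_threshold(gmm_params(0.5, 0.5, 0, 1, 1, 1))
  expect_identical(as.numeric(th), 0.5)
  # unequal weights, equal variance: closed form 0.5 + ln(7/3)
  th2 <- optimal_threshold(gmm_params(0.7, 0.3, 0, 1, 1, 1))
  expect_equal(as.numeric(th2), 0.5 + log(7 / 3), tolerance = 1e-10)
  expect_false(attr(th2, "in_interval"))  # lies beyond mu_mov = 1
  # unequal variances: agree with a bisection oracle on [0, 4]
  p <- gmm_params(0.5, 0.5, 0, 4, 1, 4)
  dd <- function(x) 0.5 * dnorm(x, 0, 1) - 0.5 * dnorm(x, 4, 2)
  oracle <- uniroot(dd, c(0, 4), tol = 1e-12)$root
  expect_equal(as.numeric(optimal_threshold(p)), oracle, tolerance = 1e-10)
  # coincident means: degenerate flag, common mean returned
  thd <- optimal_threshold(gmm_params(0.5, 0.5, 2, 2, 1, 4))
  expect_true(attr(thd, "degenerate"))
  expect_equal(as.numeric(thd), 2)
})

test_that("responsibilities are normalized posteriors", {
  p <- gmm_params(0.5, 0.5, 0, 2, 1, 1)
  expect_equal(unname(responsibilities(1, p)[1, ]), c(0.5, 0.5))
  sep <- gmm_params(0.5, 0.5, 0, 100, 1, 1)
  expect_gt(responsibilities(0, sep)[1, "p_rest"], 0.999)
  set.seed(9)
  r <- responsibilities(rnorm(1000, 1, 3), p)
  expect_equal(unname(rowSums(r)), rep(1, 1000))
  # extreme values assign to the nearer-mean component
  expect_equal(unname(responsibilities(1e6, sep)[1, "p_mov"]), 1)
})

test_that("sequential update follows the forgetting-factor recursion", {
  p <- gmm_params(0.4, 0.6, 0, 5, 1, 2)
  # alpha = 1 (L -> construction from L = Inf is approximated by adapt off)
  st <- adaptive_state(p, L = 1000)
  expect_equal(st$alpha, 999 / 1000)
  st1 <- adaptive_state(p, L = 1)   # alpha = 0: memory of one sample
  expect_equal(st1$alpha, 0)
  # a state with alpha = 1 must be a strict no-op
  st_inf <- adaptive_state(p, L = 1000)
  st_inf$alpha <- 1
  upd <- sequential_update(st_inf, 3.7)
  expect_identical(upd$params, st_inf$params)
  expect_identical(upd$theta, st_inf$theta)
  # weight sum is exactly 1 after every update
  st <- adaptive_state(p, L = 50)
  set.seed(21)
  for (x in rnorm(200, 2, 2)) {
    st <- sequential_update(st, x)
    expect_identical(st$params$w_rest + st$params$w_mov, 1)
  }
})

test_that("the update discounts history geometrically (weight ~ alpha^t)", {
  p <- gmm_params(0.4, 0.6, 0, 1000, 1, 1)
  L <- 100; a <- (L - 1) / L
  # constant input at mu_rest: p_rest = 1 exactly, so
  # w_rest,l = 1 - alpha^l (1 - w_rest,0)
  st <- classify_stream(rep(0, 400), p, L = L)
  l <- seq_len(400)
  expect_lt(max(abs(st$w_rest - (1 - a^l * 0.6))), 1e-12)
})

test_that("streaming classification matches iterated single-step updates", {
  set.seed(31)
  z <- c(rnorm(150, 1, 0.4), rnorm(150, 4, 0.8))
  init <- gmm_params(0.5, 0.5, 0.8, 4.5, 0.3, 0.9)
  st <- adaptive_state(init, L = 40)
  lab_r <- integer(length(z)); theta_r <- numeric(length(z))
  for (i in seq_along(z)) {
    theta_r[i] <- st$theta
    lab_r[i] <- as.integer(z[i] >= st$theta)
    st <- sequential_update(st, z[i])
  }
  stc <- classify_stream(z, init, L = 40)
  expect_equal(stc$theta, theta_r, tolerance = 1e-12)
  expect_identical(stc$labels, lab_r)
  expect_lt(max(abs(unlist(stc$params) - unlist(st$params))), 1e-12)
})

test_that("stationary streaming converges to the generator components", {
  set.seed(77)
  n <- 1e5
  mov <- runif(n) < 0.5
  y <- rnorm(n, ifelse(mov, 5, 1), ifelse(mov, 0.5, 0.3))
  init <- gmm_params(0.5, 0.5, 0.5, 6, 0.2, 0.5)
  st <- classify_stream(y, init, L = 1000)
  expect_lt(abs(st$params$mu_rest - 1) / 1, 0.05)
  expect_lt(abs(st$params$mu_mov - 5) / 5, 0.05)
  expect_identical(max(abs(st$w_sum - 1)), 0)
})

test_that("stream labels react to a step change within one step", {
  p <- gmm_params(0.5, 0.5, 0, 10, 1, 1)
  x <- c(rep(0, 50), rep(10, 50))
  st <- classify_stream(x, p, L = 1000)
  expect_true(all(st$labels[1:50] == 0))
  expect_true(all(st$labels[51:100] == 1))
  # theta trace stays between the running component means here
  expect_true(all(st$theta > 0 & st$theta < 10))
})

test_that("classification is invariant to affine rescaling of the problem", {
  set.seed(41)
  z <- rnorm(500, 2, 2)
  p <- gmm_params(0.45, 0.55, 0.5, 4, 0.5, 1.5)
  a <- 3.2; b <- -7
  p2 <- gmm_params(0.45, 0.55, a * 0.5 + b, a * 4 + b,
                   a^2 * 0.5, a^2 * 1.5)
  s1 <- classify_stream(z, p, L = 100)
  s2 <- classify_stream(a * z + b, p2, L = 100)
  expect_identical(s1$labels, s2$labels)
  expect_equal(s2$theta, a * s1$theta + b, tolerance = 1e-9)
})

test_that("model file serialization round-trips", {
  set.seed(51)
  models <- list(
    AnteriorDeltoid = list(IAV = emg_gmm(c(rnorm(100, 1), rnorm(60, 6)))),
    Biceps = list(WL = emg_gmm(c(rnorm(100, 2), rnorm(60, 9)))))
  path <- withr::local_tempfile(fileext = ".txt")
  write_gmm_models(models, path, meta = list(session = "s1"))
  back <- read_gmm_models(path)
  expect_equal(unlist(back$AnteriorDeltoid$IAV),
               unlist(models$AnteriorDeltoid$IAV$params), tolerance = 1e-15)
  expect_equal(unlist(back$Biceps$WL), unlist(models$Biceps$WL$params),
               tolerance = 1e-15)
})

test_that("fitted-model methods are coherent", {
  set.seed(61)
  x <- c(rnorm(400, 1, 0.5), rnorm(200, 5, 1))
  fit <- emg_gmm(x)
  expect_output(print(fit), "converged")
  expect_output(print(summary(fit)), "separation")
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  lab <- predict(fit)
  expect_true(all(lab %in% 0:1))
  expect_equal(predict(fit, newdata = fit$theta), 1L)  # boundary -> movement
  expect_equal(predict(fit, newdata = fit$theta - 1e-9), 0L)
  set.seed(1); sim <- simulate(fit, nsim = 5000)
  expect_equal(mean(sim), fit$params$w_rest * fit$params$mu_rest +
                 fit$params$w_mov * fit$params$mu_mov, tolerance = 0.1)
})
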