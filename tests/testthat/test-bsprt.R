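test_that("constrained fits have closed-form intercepts and ML sigmas", {
  t <- 1:20
  # noiseless line under its own slope: exact intercept, zero sigma
  f <- constrained_fit(t, 2 + 0.05 * t, 0.05)
  expect_equal(f$intercept, 2.0, tolerance = 1e-12)
  expect_equal(f$sigma, 0.0, tolerance = 1e-12)
  # two-point arithmetic: values (0,1) at times (1,2) under slope 0
  f2 <- constrained_fit(c(1, 2), c(0, 1), 0)
  expect_equal(f2$intercept, 0.5)
  expect_equal(f2$sigma, 0.5)
  # slope 0 reduces to the sample mean
  set.seed(81)
  y <- rnorm(50)
  expect_equal(constrained_fit(1:50, y, 0)$intercept, mean(y), tolerance = 1e-12)
  expect_error(constrained_fit(1, 1, 0), "length")
})

test_that("constrained fits recover the generating intercept and noise level", {
  set.seed(82)
  t <- 1:200
  y <- 1.5 + 0.05 * t + rnorm(200, 0, 0.7)
  f <- constrained_fit(t, y, 0.05)
  expect_lt(abs(f$intercept - 1.5), 0.2)
  expect_lt(abs(f$sigma - 0.7), 0.1)
})

test_that("the SPRT statistic is an antisymmetric Gaussian log-likelihood ratio", {
  set.seed(83)
  t <- 1:30; y <- 0.03 * t + rnorm(30)
  f1 <- constrained_fit(t, y, 0.01)
  f2 <- constrained_fit(t, y, 0.05)
  expect_equal(sprt_llr(t, y, f1, f1), 0)
  expect_equal(sprt_llr(t, y, f1, f2), -sprt_llr(t, y, f2, f1), tolerance = 1e-10)

  # single point on fit2's line, equal sigmas, fit1 off by d: llr = d^2 / (2 sigma^2)
  f2p <- make_cfit(0, 1, 0.5)
  f1p <- make_cfit(0, 1 - 0.3, 0.5)
  expect_equal(sprt_llr(1, 1, f1p, f2p), 0.3^2 / (2 * 0.25), tolerance = 1e-12)

  expect_error(sprt_llr(t, y, make_cfit(0, 0, 0), f2), "sigma > 0")
})

test_that("the bootstrap band is deterministic by seed and degenerate on constant data", {
  t <- rep(2, 10); y <- rep(1, 10)
  f1 <- make_cfit(0, 0.5, 1); f2 <- make_cfit(0, 1.5, 1)
  bd <- bootstrap_band(t, y, f1, f2, B = 50, seed = 1L)
  pt <- sprt_llr(t, y, f1, f2)
  expect_equal(bd$lower, pt, tolerance = 1e-12)
  expect_equal(bd$upper, pt, tolerance = 1e-12)

  set.seed(84)
  t2 <- 1:25; y2 <- 0.05 * t2 + rnorm(25)
  g1 <- constrained_fit(t2, y2, 0.01); g2 <- constrained_fit(t2, y2, 0.05)
  b1 <- bootstrap_band(t2, y2, g1, g2, B = 100, seed = 9L)
  b2 <- bootstrap_band(t2, y2, g1, g2, B = 100, seed = 9L)
  expect_identical(b1$draws, b2$draws)
  expect_lte(b1$lower, b1$upper)
})

test_that("bootstrap percentile bands stabilize as the resample count grows", {
  set.seed(85)
  t <- 1:40; y <- 0.05 * t + rnorm(40)
  f1 <- constrained_fit(t, y, 0.01); f2 <- constrained_fit(t, y, 0.05)
  a <- bootstrap_band(t, y, f1, f2, B = 5000, seed = 1L)
  b <- bootstrap_band(t, y, f1, f2, B = 5000, seed = 2L)
  width <- a$upper - a$lower
  expect_lt(abs(a$lower - b$lower), 0.05 * width)
  expect_lt(abs(a$upper - b$upper), 0.05 * width)
})

test_that("overwhelming evidence stops the slope SPRT at or just after min_n", {
  t <- 1:100
  y <- 0.05 * t + simulate_ar1(100L, 0, seed = 86L) * 1e-6
  res <- run_bsprt(y, b1 = 0.01, b2 = 0.05, seed = 1L)
  expect_identical(res$decision, "accept_H2")
  expect_lte(res$n_stop, 6L)

  down <- -1 * t + simulate_ar1(100L, 0, seed = 87L)
  res2 <- run_bsprt(down, b1 = 0.01, b2 = 0.05, seed = 2L)
  expect_identical(res2$decision, "accept_H1")
  expect_lt(res2$n_stop, 20L)
})

test_that("slope SPRT results are reproducible and structurally coherent", {
  y <- 0.03 * (1:100) + simulate_ar1(100L, 0.3, seed = 88L)
  a <- run_bsprt(y, seed = 5L)
  b <- run_bsprt(y, seed = 5L)
  expect_equal(a, b)
  expect_equal(length(a$llr_path), length(a$steps))
  expect_equal(a$steps[length(a$steps)], a$n_stop)
  expect_true(all(a$band_lower <= a$band_upper, na.rm = TRUE))
  # the point statistic always lies inside its own bootstrap band envelope
  expect_true(all(a$llr_path >= a$band_lower - (a$band_upper - a$band_lower),
                  na.rm = TRUE))
  expect_error(run_bsprt(rnorm(10), max_n = 50), "exhausted")
})

test_that("the standard SPRT compares the point statistic with the boundaries directly", {
  y <- 0.05 * (1:100) + simulate_ar1(100L, 0, seed = 89L)
  res <- run_bsprt(y, use_bootstrap = FALSE, b1 = 0, b2 = 0.05)
  expect_true(all(is.na(res$band_lower)))
  final <- res$llr_path[length(res$llr_path)]
  expect_true(res$forced_call || abs(final) >= log(19) - 1e-9)
  # bootstrap calibration can only delay the decision relative to the point rule
  boot <- run_bsprt(y, use_bootstrap = TRUE, b1 = 0, b2 = 0.05, seed = 3L)
  expect_gte(boot$n_stop, res$n_stop)
})

test_that("H2 acceptance rises with the true slope for the bootstrap SPRT", {
  r <- simulate_table1(effects = c(0, 0.04, 0.075), phis = 0, reps = 40L,
                       methods = "bootstrap", seed = 90L)
  expect_true(all(diff(r$accept_h2) >= 0))
  expect_lt(r$accept_h2[1], 0.2)
  expect_gt(r$accept_h2[3], 0.8)
  expect_equal(r$accept_h1 + r$accept_h2, rep(1, 3))
})
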