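test_that("OLS dummy test matches the two-group closed form and lm()", {
  tr <- make_trial(c(0, 1, 2, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  res <- ols_dummy_test(tr)
  expect_equal(res$estimate, 1.0, tolerance = 1e-12)
  expect_equal(res$se, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$statistic, sqrt(1.5), tolerance = 1e-12)

  # cross-check against lm on a random fixture
  set.seed(31)
  tr2 <- make_trial(rnorm(40), rep(0:1, each = 20))
  res2 <- ols_dummy_test(tr2)
  sm <- summary(lm(value ~ dummy, data = tr2))$coefficients["dummy", ]
  expect_equal(res2$estimate, unname(sm["Estimate"]), tolerance = 1e-10)
  expect_equal(res2$se, unname(sm["Std. Error"]), tolerance = 1e-10)
  expect_equal(res2$p_value, unname(sm["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("OLS test is invariant to location shifts and zero for identical arms", {
  set.seed(32)
  tr <- make_trial(rnorm(30), rep(0:1, 15))
  shifted <- tr; shifted$value <- tr$value + 17.3
  a <- ols_dummy_test(tr); b <- ols_dummy_test(shifted)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-10)

  same <- make_trial(rep(c(1, 2, 3), 2), rep(0:1, each = 3))
  expect_equal(ols_dummy_test(same)$estimate, 0)
})

test_that("degenerate designs are refused", {
  expect_error(ols_dummy_test(make_trial(rnorm(10), rep(0, 10))), "degenerate")
  expect_error(gls_ar1_test(make_trial(rnorm(10), rep(1, 10))), "degenerate")
})

test_that("GLS with known phi equals the closed-form generalized least squares solution", {
  set.seed(42)
  n <- 12L
  tr <- make_trial(rnorm(n), rep(0:1, each = 6))
  V <- 0.5^abs(outer(1:n, 1:n, "-"))
  X <- cbind(1, tr$dummy)
  b <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% tr$value)
  res <- gls_ar1_test(tr, fixed_phi = 0.5)
  expect_equal(res$estimate, b[2, 1], tolerance = 1e-8)
})

test_that("profile-ML GLS agrees with nlme::gls on the same data", {
  set.seed(43)
  x <- simulate_ar1(400L, 0.5, seed = 44L)
  tr <- assemble_trial(x, design_spec(4, 50, 0), start = 1L)
  res <- gls_ar1_test(tr)
  fit <- nlme::gls(value ~ dummy, data = tr,
                   correlation = nlme::corAR1(form = ~1), method = "ML")
  tt <- summary(fit)$tTable["dummy", ]
  expect_equal(res$estimate, unname(tt["Value"]), tolerance = 1e-5)
  expect_equal(res$se, unname(tt["Std.Error"]), tolerance = 1e-4)
  expect_equal(res$est_phi,
               unname(coef(fit$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-4)
})

test_that("GLS reduces to OLS when the data are serially uncorrelated", {
  x <- simulate_ar1(400L, 0, seed = 45L)
  tr <- assemble_trial(x, design_spec(4, 50, 0), start = 1L)
  g <- gls_ar1_test(tr); o <- ols_dummy_test(tr)
  expect_lt(abs(g$est_phi), 0.15)
  # the null estimate hovers near zero, so compare on the standard-error scale
  expect_lt(abs(g$estimate - o$estimate) / o$se, 0.1)
  expect_lt(abs(g$se - o$se) / o$se, 0.05)
})

test_that("GLS recovers the residual autocorrelation strength on average", {
  set.seed(46)
  phis <- replicate(200, {
    x <- simulate_ar1(400L, 0.5)
    tr <- assemble_trial(x, design_spec(4, 50, 0), start = 1L)
    gls_ar1_test(tr)$est_phi
  })
  expect_gt(mean(phis), 0.45)
  expect_lt(mean(phis), 0.55)
})

test_that("true-time gap mode matches consecutive mode on gapless data and runs with gaps", {
  x <- simulate_ar1(200L, 0.6, seed = 47L)
  tr <- assemble_trial(x, design_spec(2, 50, 0), start = 1L)
  a <- gls_ar1_test(tr, gap_mode = "consecutive")
  b <- gls_ar1_test(tr, gap_mode = "true_time")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-6)
  expect_equal(a$est_phi, b$est_phi, tolerance = 1e-5)

  gaps <- assemble_trial(simulate_ar1(400L, 0.6, seed = 48L),
                         design_spec(2, 50, 50), start = 1L)
  g <- gls_ar1_test(gaps, gap_mode = "true_time")
  expect_true(abs(g$est_phi) < 1)
  expect_true(g$p_value >= 0 && g$p_value <= 1)
})

test_that("Newey-West variance reproduces hand-computed Bartlett sums", {
  y <- c(1, -1, 1, -1)
  m <- lm(y ~ 1)
  # lag 0: variance of the mean = sum(e^2)/n^2 = 0.25
  expect_equal(newey_west_vcov(m, lag = 0, prewhite = FALSE)[1, 1], 0.25,
               tolerance = 1e-12)
  # lag 1: S = 1 + 2 * 0.5 * (-0.75) = 0.25; var = S/n = 0.0625
  expect_equal(newey_west_vcov(m, lag = 1, prewhite = FALSE)[1, 1], 0.0625,
               tolerance = 1e-12)
  expect_error(newey_west_vcov(m, lag = 4, prewhite = FALSE), "lag")
})

test_that("HAC standard errors collapse toward OLS under independence", {
  set.seed(49)
  tr <- make_trial(rnorm(200), rep(0:1, 100))
  o <- ols_dummy_test(tr)
  nw <- newey_west_test(tr, lag = 0, prewhite = FALSE)
  expect_equal(nw$estimate, o$estimate, tolerance = 1e-10)
  expect_lt(abs(nw$se - o$se) / o$se, 0.05)
})

test_that("test results carry a consistent statistic and printable summary", {
  x <- simulate_ar1(400L, 0.5, seed = 50L)
  tr <- assemble_trial(x, design_spec(4, 50, 0), start = 1L)
  for (res in list(ols_dummy_test(tr), gls_ar1_test(tr), newey_west_test(tr))) {
    expect_equal(res$statistic, res$estimate / res$se, tolerance = 1e-8)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
    expect_output(print(res), res$method, fixed = TRUE)
  }
  df <- as.data.frame(gls_ar1_test(tr))
  expect_identical(names(df)[1], "method")
})
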