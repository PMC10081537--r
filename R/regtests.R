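# Intervention-effect tests on carved trial data. All three tests regress
# the response on the 0/1 arm dummy (0 = A, 1 = B) and report a two-sided t
# test on the dummy coefficient with n - 2 degrees of freedom; they differ in
# how (or whether) serial correlation in the residuals is handled.

new_test_result <- function(estimate, se, statistic, p_value, method,
                            est_phi = NA_real_, n) {
  structure(list(estimate = unname(estimate), se = unname(se),
                 statistic = unname(statistic), p_value = unname(p_value),
                 method = method, est_phi = unname(est_phi), n = n),
            class = "nof1_test")
}

#' @export
print.nof1_test <- function(x, ...) {
  cat(sprintf("%s intervention-effect test (n = %d)\n", x$method, x$n))
  cat(sprintf("  dummy coefficient: %.4f (se %.4f), t = %.3f, p = %.4g\n",
              x$estimate, x$se, x$statistic, x$p_value))
  if (is.finite(x$est_phi))
    cat(sprintf("  estimated residual lag-1 correlation: %.3f\n", x$est_phi))
  invisible(x)
}

#' @export
as.data.frame.nof1_test <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             statistic = x$statistic, p_value = x$p_value,
             est_phi = x$est_phi, n = x$n)
}

check_trial <- function(trial) {
  stopifnot(inherits(trial, "nof1_trial") || is.data.frame(trial))
  if (!all(c("value", "dummy") %in% names(trial)))
    stop("trial data must have `value` and `dummy` columns", call. = FALSE)
  d <- trial$dummy
  if (length(unique(d)) < 2L)
    stop("degenerate design: both arms must be present", call. = FALSE)
  if (nrow(trial) < 3L)
    stop("at least 3 measurements are required", call. = FALSE)
  invisible(trial)
}

#' Naive OLS test of an intervention effect
#'
#' Ordinary least squares of the response on the arm dummy
#' (intercept + dummy), ignoring serial correlation entirely; this is the
#' test whose false-positive rate inflates with positive autocorrelation and
#' with washout periods. Because the design matrix is an intercept and one
#' 0/1 column, the fit reduces to the two-group closed form: the dummy
#' coefficient is `mean(B) - mean(A)` and the standard error uses the pooled
#' residual variance.
#'
#' @param trial trial data with `value` and `dummy` columns
#'   (see [assemble_trial()]).
#' @return a `nof1_test` result (`method = "OLS"`).
#' @export
ols_dummy_test <- function(trial) {
  check_trial(trial)
  y <- trial$value
  d <- trial$dummy
  n <- length(y)
  yB <- y[d == 1L]; yA <- y[d == 0L]
  nA <- length(yA); nB <- length(yB)
  est <- mean(yB) - mean(yA)
  ssr <- sum((yA - mean(yA))^2) + sum((yB - mean(yB))^2)
  s2 <- ssr / (n - 2L)
  se <- sqrt(s2 * (1 / nA + 1 / nB))
  stat <- if (se > 0) est / se else 0
  p <- 2 * stats::pt(-abs(stat), df = n - 2L)
  new_test_result(est, se, stat, p, "OLS", n = n)
}

# AR(1) whitening transform of (y, X) for observation gaps `dt` (dt[i] is the
# time step from observation i-1 to i; dt[1] unused). Marginal-variance
# parameterization: the first row keeps marginal scale, later rows are
# (z_i - phi^dt z_{i-1}) / sqrt(1 - phi^(2 dt)).
whiten_ar1 <- function(y, X, phi, dt) {
  n <- length(y)
  a <- phi^dt[-1L]
  s <- sqrt(1 - a^2)
  ys <- c(y[1L], (y[-1L] - a * y[-n]) / s)
  Xs <- rbind(X[1L, ], (X[-1L, , drop = FALSE] - a * X[-n, , drop = FALSE]) / s)
  list(y = ys, X = Xs, logdet_corr = sum(log(s^2)))
}

# profile log-likelihood of phi (ML, gaussian AR(1) residuals), up to a
# constant: coefficients and sigma^2 are concentrated out
profile_ll_ar1 <- function(phi, y, X, dt) {
  w <- whiten_ar1(y, X, phi, dt)
  fit <- stats::.lm.fit(w$X, w$y)
  rss <- sum(fit$residuals^2)
  -length(y) / 2 * log(rss / length(y)) - 0.5 * w$logdet_corr
}

#' GLS test with AR(1) residual correlation
#'
#' Maximum-likelihood joint estimation of the intercept, the dummy
#' coefficient, the residual standard deviation and the residual lag-1
#' autocorrelation `phi`, under AR(1) errors. `phi` is profiled over
#' (-0.99, 0.99) with an inner closed-form whitened least-squares fit, so the
#' optimization is one-dimensional and deterministic.
#'
#' `gap_mode` controls how washout gaps in the `time` column are treated:
#' `"consecutive"` (default) indexes the correlation by observation order,
#' i.e. measurements on either side of a washout are treated as adjacent --
#' the behavior of standard AR(1) regression software when the data are
#' handed over as one unbroken vector, and the mode in which washouts distort
#' the correlation estimate. `"true_time"` uses the recorded times with
#' correlation `phi^dt` across a gap of `dt` units, the principled
#' alternative.
#'
#' @param trial trial data (`time`, `value`, `dummy`).
#' @param gap_mode `"consecutive"` or `"true_time"`.
#' @param fixed_phi if supplied, `phi` is held at this value instead of being
#'   estimated (used for closed-form verification).
#' @return a `nof1_test` result (`method = "GLS_AR1"`) with `est_phi` set.
#' @export
gls_ar1_test <- function(trial, gap_mode = c("consecutive", "true_time"),
                         fixed_phi = NULL) {
  gap_mode <- match.arg(gap_mode)
  check_trial(trial)
  y <- trial$value
  n <- length(y)
  X <- cbind(intercept = 1, dummy = trial$dummy)
  dt <- if (gap_mode == "true_time" && !is.null(trial$time)) {
    if (any(diff(trial$time) <= 0))
      stop("`time` must be strictly increasing for gap_mode = \"true_time\"",
           call. = FALSE)
    c(1, diff(trial$time))
  } else rep(1, n)
  if (is.null(fixed_phi)) {
    opt <- stats::optimize(profile_ll_ar1, c(-0.99, 0.99), y = y, X = X,
                           dt = dt, maximum = TRUE, tol = 1e-7)
    phi <- opt$maximum
  } else {
    phi <- check_number(fixed_phi, "fixed_phi", lower = -1, upper = 1,
                        open_lower = TRUE, open_upper = TRUE)
  }
  w <- whiten_ar1(y, X, phi, dt)
  fit <- stats::lm.fit(w$X, w$y)
  rss <- sum(fit$residuals^2)
  # ML residual variance with the same small-sample scaling nlme's gls uses
  # for coefficient covariances (RSS / (n - p))
  s2 <- rss / (n - 2L)
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(s2 * XtXinv[2L, 2L])
  est <- fit$coefficients[2L]
  stat <- if (se > 0) est / se else 0
  p <- 2 * stats::pt(-abs(stat), df = n - 2L)
  new_test_result(est, se, stat, p, "GLS_AR1", est_phi = phi, n = n)
}

# automatic truncation lag for the Bartlett kernel without prewhitening
nw_auto_lag <- function(n) as.integer(floor(4 * (n / 100)^(2 / 9)))

#' Newey-West covariance of regression coefficients
#'
#' Thin wrapper around [sandwich::NeweyWest()] fixing the conventions used
#' throughout this package: no finite-sample adjustment, and - when a lag is
#' given explicitly or prewhitening is off - the plain Bartlett-kernel sum
#' \eqn{S = \Gamma_0 + \sum_{j=1}^{L} (1 - j/(L+1)) (\Gamma_j + \Gamma_j')}
#' sandwiched between \eqn{(X'X)^{-1}} factors. With `prewhite = TRUE` and no
#' explicit lag, sandwich's VAR(1) prewhitening and automatic bandwidth are
#' used. With `prewhite = FALSE` and no explicit lag, the truncation lag
#' defaults to `floor(4 (n/100)^{2/9})`.
#'
#' @param model a fitted [stats::lm()] model.
#' @param lag Bartlett truncation lag `L >= 0`, or `NULL` for automatic.
#' @param prewhite logical; VAR(1)-prewhiten the score contributions.
#' @return coefficient covariance matrix.
#' @export
newey_west_vcov <- function(model, lag = NULL, prewhite = TRUE) {
  n <- length(stats::residuals(model))
  if (!is.null(lag)) {
    lag <- check_number(lag, "lag", lower = 0, integer = TRUE)
    if (lag >= n) stop("`lag` must be smaller than the number of observations",
                       call. = FALSE)
  } else if (!prewhite) {
    lag <- nw_auto_lag(n)
  }
  sandwich::NeweyWest(model, lag = lag, prewhite = prewhite, adjust = FALSE)
}

#' Serial-correlation-robust (Newey-West) test of an intervention effect
#'
#' OLS point estimate of the dummy coefficient with a
#' heteroskedasticity-and-autocorrelation-consistent (HAC) standard error
#' from the Bartlett-kernel sandwich estimator; the robust correction leaves
#' the estimate untouched and only widens the standard error to account for
#' serially correlated residuals.
#'
#' @inheritParams ols_dummy_test
#' @inheritParams newey_west_vcov
#' @return a `nof1_test` result (`method = "NEWEY_WEST"`).
#' @export
newey_west_test <- function(trial, lag = NULL, prewhite = TRUE) {
  check_trial(trial)
  n <- nrow(trial)
  fit <- stats::lm(value ~ dummy, data = trial)
  V <- newey_west_vcov(fit, lag = lag, prewhite = prewhite)
  est <- stats::coef(fit)[["dummy"]]
  se <- sqrt(V["dummy", "dummy"])
  stat <- if (se > 0) est / se else 0
  p <- 2 * stats::pt(-abs(stat), df = n - 2L)
  new_test_result(est, se, stat, p, "NEWEY_WEST", n = n)
}
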