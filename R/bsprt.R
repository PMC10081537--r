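# Bootstrap-calibrated SPRT for a regression slope ("bSPRT"): quickest
# single-subject outcome determination. The target parameter is the slope of
# outcome on time since intervention start; the y-intercept and residual sd
# are nuisance parameters whose estimation noise destabilizes the naive
# sequential likelihood ratio. The bSPRT replaces the point statistic with a
# bootstrap confidence band (pair resampling, likelihood parameters frozen at
# the observed-data estimates) and only terminates when the *conservative*
# limit of the band crosses a Wald boundary.

#' Constrained regression fit under a hypothesized slope
#'
#' Maximum-likelihood fit of `values ~ intercept + slope * times` with the
#' slope held fixed: the intercept is `mean(values - slope * times)` and the
#' residual sd is the ML estimate (divisor n).
#'
#' @param times,values numeric vectors of equal length >= 2.
#' @param slope hypothesized slope (held fixed).
#' @return object of class `nof1_cfit`: `slope`, `intercept`, `sigma`.
#' @export
constrained_fit <- function(times, values, slope) {
  if (length(times) != length(values) || length(values) < 2L)
    stop("`times` and `values` must have equal length >= 2", call. = FALSE)
  slope <- check_number(slope, "slope")
  intercept <- mean(values - slope * times)
  r <- values - intercept - slope * times
  structure(list(slope = slope, intercept = intercept,
                 sigma = sqrt(mean(r^2))),
            class = "nof1_cfit")
}

#' SPRT statistic: Gaussian log-likelihood ratio of two slope fits
#'
#' Sum over observations of the difference in Gaussian log-densities under
#' `fit2` (H2) and `fit1` (H1):
#' \eqn{\sum_t [\log\phi(y_t; a_2 + b_2 t, \sigma_2) -
#'              \log\phi(y_t; a_1 + b_1 t, \sigma_1)]}.
#' Positive values favor H2.
#'
#' @param times,values the data.
#' @param fit1,fit2 [constrained_fit()] objects under the H1 and H2 slopes.
#' @return scalar log-likelihood ratio.
#' @export
sprt_llr <- function(times, values, fit1, fit2) {
  stopifnot(inherits(fit1, "nof1_cfit"), inherits(fit2, "nof1_cfit"))
  if (fit1$sigma <= 0 || fit2$sigma <= 0)
    stop("degenerate likelihood: both fits need sigma > 0", call. = FALSE)
  sum(stats::dnorm(values, fit2$intercept + fit2$slope * times, fit2$sigma, log = TRUE)) -
    sum(stats::dnorm(values, fit1$intercept + fit1$slope * times, fit1$sigma, log = TRUE))
}

# vectorized LLR over B pair-resamples with frozen fits; returns B values.
# Equivalent to sprt_llr() applied to each resampled (time, value) set.
boot_llr_draws <- function(times, values, fit1, fit2, B) {
  n <- length(values)
  # per-point log-density difference: a resample's LLR is a sum of n of
  # these drawn with replacement
  c_i <- stats::dnorm(values, fit2$intercept + fit2$slope * times, fit2$sigma, log = TRUE) -
    stats::dnorm(values, fit1$intercept + fit1$slope * times, fit1$sigma, log = TRUE)
  idx <- sample.int(n, n * B, replace = TRUE)
  colSums(matrix(c_i[idx], nrow = n, ncol = B))
}

#' Bootstrap confidence band for the SPRT statistic
#'
#' Draws `B` resamples of the accumulated (time, value) *pairs* with
#' replacement, computes the SPRT statistic on each resample with the
#' likelihood parameters frozen at the observed-data fits (not re-estimated
#' per resample), and returns the empirical `lo_pct`/`hi_pct` percentiles.
#' Resampling pairs keeps each outcome attached to its design point, so the
#' band reflects the sampling noise of the statistic including the
#' nuisance-parameter contribution.
#'
#' @inheritParams sprt_llr
#' @param B number of resamples (default 100).
#' @param lo_pct,hi_pct band percentiles (defaults 5 and 95).
#' @param seed optional seed (same seed, same band, caller's RNG stream
#'   untouched).
#' @return object of class `nof1_band`: `lower`, `upper`, `B`, `lo_pct`,
#'   `hi_pct`, and `draws` (the B resampled statistics).
#' @export
bootstrap_band <- function(times, values, fit1, fit2, B = 100L,
                           lo_pct = 5, hi_pct = 95, seed = NULL) {
  B <- check_number(B, "B", lower = 2, integer = TRUE)
  if (length(values) < 2L) stop("need at least 2 observations", call. = FALSE)
  stopifnot(lo_pct < hi_pct)
  draws <- with_seed(seed, boot_llr_draws(times, values, fit1, fit2, B))
  q <- unname(stats::quantile(draws, c(lo_pct, hi_pct) / 100))
  structure(list(lower = q[1L], upper = q[2L], B = B,
                 lo_pct = lo_pct, hi_pct = hi_pct, draws = draws),
            class = "nof1_band")
}

# point LLR and the pair of constrained fits, under either sigma convention.
# "pooled": one ML residual sd (divisor n) from the unconstrained OLS fit is
# used in both hypothesis densities, so the LLR contrasts the two mean
# structures against a common noise scale. "per_hypothesis": each fit keeps
# its own ML sigma.
step_fits <- function(times, values, b1, b2, sigma_pooling) {
  f1 <- constrained_fit(times, values, b1)
  f2 <- constrained_fit(times, values, b2)
  if (sigma_pooling == "pooled") {
    ols <- stats::.lm.fit(cbind(1, times), values)
    s <- sqrt(mean(ols$residuals^2))
    f1$sigma <- f2$sigma <- s
  }
  list(f1 = f1, f2 = f2)
}

#' Bootstrap-calibrated SPRT for a regression slope
#'
#' Sequentially tests H1: slope = `b1` against H2: slope = `b2` (`b1 < b2`)
#' on a stream of (time, value) measurements. At each n from `min_n` on, the
#' intercept and residual sd are (re-)estimated from the accumulated data,
#' the SPRT statistic (log-likelihood ratio of the two constrained fits) is
#' computed, and:
#' \itemize{
#' \item with `use_bootstrap = TRUE` (the bSPRT), a `B`-resample percentile
#'   band for the statistic is computed with frozen fits; H2 is accepted when
#'   the band's *lower* limit reaches the upper Wald boundary, H1 when the
#'   band's *upper* limit reaches the lower boundary;
#' \item with `use_bootstrap = FALSE` (the standard SPRT comparator), the
#'   point statistic is compared with the boundaries directly.
#' }
#' If no boundary is crossed by `max_n`, a decision is forced: by the sign of
#' the statistic (`forced = "sign"`) or by the nearer boundary
#' (`"nearest"`). The default `min_n` is 5 for the bootstrap variant (the
#' band needs a non-degenerate resampling distribution) and 3 for the
#' standard one.
#'
#' By default (`sigma_pooling = "pooled"`) both hypothesis densities use a
#' single ML residual sd taken from the unconstrained OLS fit, so the
#' statistic contrasts the two mean structures against a common noise scale;
#' `"per_hypothesis"` uses each constrained fit's own ML sd.
#'
#' @param values outcome measurements (at least `max_n` must be available).
#' @param times measurement times (default `1, 2, ...`).
#' @param b1,b2 hypothesized slopes, `b1 < b2`.
#' @param alpha,beta Wald error rates.
#' @param B bootstrap resamples per step.
#' @param min_n first n at which the test is evaluated.
#' @param max_n truncation limit.
#' @param use_bootstrap `TRUE` for the bSPRT, `FALSE` for the standard SPRT.
#' @param sigma_pooling `"pooled"` or `"per_hypothesis"` (see Details).
#' @param lo_pct,hi_pct band percentiles.
#' @param forced forced-decision rule at truncation.
#' @param seed optional seed for the bootstrap draws.
#' @return object of class `nof1_bsprt`: `decision`, `n_stop`, `llr_path`
#'   (statistic at each evaluated n), `band_lower`/`band_upper` (NA for the
#'   standard SPRT), `slope_path` (unconstrained OLS slope at each evaluated
#'   n), `est_sercor` (lag-1 autocorrelation of the OLS residuals at
#'   stopping), `forced_call`, `boundaries`, `steps` (the evaluated n's).
#' @export
run_bsprt <- function(values, times = seq_along(values), b1 = 0.01, b2 = 0.05,
                      alpha = 0.05, beta = 0.05, B = 100L,
                      min_n = if (use_bootstrap) 5L else 3L, max_n = length(values),
                      use_bootstrap = TRUE,
                      sigma_pooling = c("pooled", "per_hypothesis"),
                      lo_pct = 5, hi_pct = 95,
                      forced = c("sign", "nearest"), seed = NULL) {
  sigma_pooling <- match.arg(sigma_pooling)
  forced <- match.arg(forced)
  if (b1 >= b2) stop("need b1 < b2", call. = FALSE)
  bd <- wald_boundaries(alpha, beta)
  max_n <- check_number(max_n, "max_n", lower = 3, integer = TRUE)
  min_n <- check_number(min_n, "min_n", lower = 3, integer = TRUE)
  if (min_n > max_n) stop("min_n must not exceed max_n", call. = FALSE)
  if (length(values) < max_n || length(times) < max_n)
    stop(sprintf("measurement stream exhausted: %d observations supplied, max_n = %d",
                 length(values), max_n), call. = FALSE)
  with_seed(seed, {
    steps <- min_n:max_n
    k <- length(steps)
    llr_path <- slope_path <- band_lo <- band_hi <- rep(NA_real_, k)
    decision <- NULL
    forced_call <- FALSE
    for (j in seq_len(k)) {
      n <- steps[j]
      tt <- times[seq_len(n)]
      yy <- values[seq_len(n)]
      fits <- step_fits(tt, yy, b1, b2, sigma_pooling)
      llr <- sprt_llr(tt, yy, fits$f1, fits$f2)
      llr_path[j] <- llr
      # unconstrained OLS slope, recorded for the slope trajectory
      ols <- stats::.lm.fit(cbind(1, tt), yy)
      slope_path[j] <- ols$coefficients[2L]
      if (use_bootstrap) {
        draws <- boot_llr_draws(tt, yy, fits$f1, fits$f2, B)
        q <- unname(stats::quantile(draws, c(lo_pct, hi_pct) / 100))
        band_lo[j] <- q[1L]
        band_hi[j] <- q[2L]
        if (q[1L] >= bd$upper) decision <- "accept_H2"
        else if (q[2L] <= bd$lower) decision <- "accept_H1"
      } else {
        if (llr >= bd$upper) decision <- "accept_H2"
        else if (llr <= bd$lower) decision <- "accept_H1"
      }
      if (!is.null(decision)) break
    }
    if (is.null(decision)) {
      forced_call <- TRUE
      j <- k
      llr <- llr_path[k]
      decision <- switch(forced,
        sign = if (llr > 0) "accept_H2" else "accept_H1",
        nearest = if ((bd$upper - llr) < (llr - bd$lower)) "accept_H2" else "accept_H1")
    }
    n_stop <- steps[j]
    e <- stats::.lm.fit(cbind(1, times[seq_len(n_stop)]),
                        values[seq_len(n_stop)])$residuals
    structure(list(
      decision = decision, n_stop = n_stop,
      llr_path = llr_path[seq_len(j)],
      band_lower = band_lo[seq_len(j)], band_upper = band_hi[seq_len(j)],
      slope_path = slope_path[seq_len(j)],
      est_sercor = lag1_autocor(e),
      forced_call = forced_call, boundaries = bd, steps = steps[seq_len(j)],
      b1 = b1, b2 = b2, use_bootstrap = use_bootstrap),
      class = "nof1_bsprt")
  })
}

#' @export
print.nof1_bsprt <- function(x, ...) {
  cat(sprintf("%s slope SPRT (H1: b = %g, H2: b = %g): %s at n = %d%s\n",
              if (x$use_bootstrap) "Bootstrap-calibrated" else "Standard",
              x$b1, x$b2, x$decision, x$n_stop,
              if (x$forced_call) " (forced at truncation)" else ""))
  cat(sprintf("  final statistic %.3f; OLS slope %.4f; residual lag-1 cor %.3f\n",
              x$llr_path[length(x$llr_path)],
              x$slope_path[length(x$slope_path)], x$est_sercor))
  invisible(x)
}

#' Operating characteristics of the slope SPRT over an effect/correlation grid
#'
#' For every combination of true slope in `effects` and AR(1) residual
#' correlation in `phis`, simulates `reps` measurement series
#' `y_t = effect * t + e_t` (with `e_t` a unit-marginal-variance AR(1)
#' process on times 1, 2, ...), runs the requested slope-SPRT variants on
#' each series, and summarizes stopping sample sizes, decision fractions and
#' the residual lag-1 correlation at stopping. Both variants are run on the
#' same simulated series, so method contrasts are paired.
#'
#' The default hypothesized slopes here are `b1 = 0` (no trend) and
#' `b2 = 0.05`, the null-versus-effect pair under which the intermediate
#' effect 0.025 sits exactly at the indifference point.
#'
#' @param effects true slopes to simulate.
#' @param phis AR(1) residual correlation strengths.
#' @param b1,b2 hypothesized slopes.
#' @param alpha,beta Wald error rates.
#' @param B bootstrap resamples per step.
#' @param reps simulated series per (effect, phi) setting.
#' @param max_n truncation limit (and simulated series length).
#' @param methods subset of `c("standard", "bootstrap")`.
#' @param sigma_pooling passed to [run_bsprt()].
#' @param seed optional seed.
#' @return data frame with one row per (effect, phi, method):
#'   `effect`, `phi`, `method`, `mean_ss`, `sd_ss`, `accept_h1`, `accept_h2`,
#'   `mean_sercor`, `sd_sercor`, `reps`.
#' @export
simulate_table1 <- function(effects = c(0, 0.01, 0.025, 0.04, 0.05, 0.075),
                            phis = c(0, 0.5), b1 = 0, b2 = 0.05,
                            alpha = 0.05, beta = 0.05, B = 100L, reps = 100L,
                            max_n = 100L, methods = c("standard", "bootstrap"),
                            sigma_pooling = "pooled", seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  reps <- check_number(reps, "reps", lower = 1, integer = TRUE)
  with_seed(seed, {
    out <- list()
    for (phi in phis) for (eff in effects) {
      ss <- acc2 <- sercor <- matrix(NA_real_, reps, length(methods),
                                     dimnames = list(NULL, methods))
      for (r in seq_len(reps)) {
        y <- eff * seq_len(max_n) + simulate_ar1(max_n, phi)
        for (m in methods) {
          res <- run_bsprt(y, b1 = b1, b2 = b2, alpha = alpha, beta = beta,
                           B = B, max_n = max_n,
                           use_bootstrap = (m == "bootstrap"),
                           sigma_pooling = sigma_pooling)
          ss[r, m] <- res$n_stop
          acc2[r, m] <- res$decision == "accept_H2"
          sercor[r, m] <- res$est_sercor
        }
      }
      for (m in methods) {
        out[[length(out) + 1L]] <- data.frame(
          effect = eff, phi = phi, method = m,
          mean_ss = mean(ss[, m]), sd_ss = stats::sd(ss[, m]),
          accept_h1 = 1 - mean(acc2[, m]), accept_h2 = mean(acc2[, m]),
          mean_sercor = mean(sercor[, m]), sd_sercor = stats::sd(sercor[, m]),
          reps = reps)
      }
    }
    do.call(rbind, out)
  })
}
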