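#' Simulate a stationary AR(1) Gaussian series
#'
#' Generates a realization of the first-order autoregressive process
#' \eqn{X_t = \phi X_{t-1} + e_t} used as the outcome model for single-subject
#' monitoring data. By default the innovation variance is
#' \eqn{(1-\phi^2)\,\sigma^2} so that the *marginal* (stationary) variance of
#' the series equals \eqn{\sigma^2} for every \eqn{\phi}: intervention effect
#' sizes expressed in standard-deviation units then mean the same thing at
#' every serial-correlation strength. The first value is drawn from the
#' stationary distribution, so the series is exactly stationary from t = 1
#' (no burn-in).
#'
#' @param n number of time points (positive integer).
#' @param phi lag-1 autocorrelation, in (-1, 1).
#' @param marginal_sd standard deviation of the stationary distribution
#'   (default 1).
#' @param seed optional integer seed; the same seed reproduces the series
#'   bit for bit and the caller's RNG stream is left untouched.
#' @param scale `"marginal"` (default) normalizes to unit-`marginal_sd`
#'   marginal variance; `"innovation"` uses innovation sd `marginal_sd`
#'   directly (marginal variance then grows as \eqn{1/(1-\phi^2)}).
#' @return numeric vector of length `n`.
#' @examples
#' x <- simulate_ar1(1000, phi = 0.75, seed = 1)
#' var(x)  # close to 1 by construction
#' @export
simulate_ar1 <- function(n, phi, marginal_sd = 1, seed = NULL,
                         scale = c("marginal", "innovation")) {
  scale <- match.arg(scale)
  n <- check_number(n, "n", lower = 1, integer = TRUE)
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || abs(phi) >= 1)
    stop("`phi` must satisfy |phi| < 1 (stationarity)", call. = FALSE)
  marginal_sd <- check_number(marginal_sd, "marginal_sd", lower = 0, open_lower = TRUE)
  with_seed(seed, {
    if (scale == "marginal") {
      sd_marg <- marginal_sd
      sd_innov <- marginal_sd * sqrt(1 - phi^2)
    } else {
      sd_innov <- marginal_sd
      sd_marg <- marginal_sd / sqrt(1 - phi^2)
    }
    x1 <- stats::rnorm(1L, 0, sd_marg)
    if (n == 1L) return(x1)
    e <- stats::rnorm(n - 1L, 0, sd_innov)
    if (phi == 0) return(c(x1, e))
    c(x1, as.numeric(stats::filter(e, phi, method = "recursive", init = x1)))
  })
}

#' Rolling mean with two-standard-error bands
#'
#' Computes, for every window of `window` consecutive values, the window mean
#' and the mean plus/minus twice the standard error of the mean
#' (`2 * sd(window) / sqrt(window)`). These are the diagnostic bands that make
#' chance "local mean differences" in serially correlated series visible: with
#' strong positive autocorrelation, two distant windows often have
#' non-overlapping bands even though no effect is present.
#'
#' @param values numeric series.
#' @param window window length, an integer in `[2, length(values)]`
#'   (default 25).
#' @return data frame with columns `time` (index of the window start),
#'   `mean`, `lower`, `upper`; one row per window
#'   (`length(values) - window + 1` rows).
#' @export
rolling_band <- function(values, window = 25L) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("`values` must be a numeric vector of length >= 2", call. = FALSE)
  window <- check_number(window, "window", lower = 2, upper = length(values),
                         integer = TRUE)
  m <- zoo::rollmean(values, window, align = "left")
  m2 <- zoo::rollmean(values^2, window, align = "left")
  # window variance with the usual n-1 divisor; clamp tiny negative rounding
  v <- pmax(0, (m2 - m^2) * window / (window - 1))
  half <- 2 * sqrt(v) / sqrt(window)
  data.frame(time = seq_along(m), mean = m, lower = m - half, upper = m + half)
}

#' Write / read a series as a two-column CSV
#'
#' Plain-text interchange format for simulated series: header `time,value`,
#' one row per measurement.
#'
#' @param values numeric series.
#' @param path file path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns the numeric series (time order is restored from the `time`
#'   column).
#' @export
write_series_csv <- function(values, path) {
  utils::write.csv(data.frame(time = seq_along(values), value = values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "value") %in% names(d)))
    stop("series CSV must have columns `time` and `value`", call. = FALSE)
  d$value[order(d$time)]
}
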