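# Wald SPRT machinery for binary outcomes, plus the aggregated
# personalized-studies response-rate procedure: run personalized trials one
# individual at a time, score each as responder / non-responder by a
# within-trial significance test, and test the running response rate
# sequentially against two hypothesized rates.

#' Wald SPRT decision boundaries
#'
#' The classical sequential probability ratio test compares the cumulative
#' log-likelihood ratio (H2 over H1) with `lower = log(beta / (1 - alpha))`
#' and `upper = log((1 - beta) / alpha)`; crossing the upper boundary accepts
#' H2, crossing the lower accepts H1.
#'
#' @param alpha type-I error rate in (0, 1).
#' @param beta type-II error rate in (0, 1).
#' @return object of class `sprt_boundaries` with elements `alpha`, `beta`,
#'   `lower`, `upper`.
#' @examples
#' wald_boundaries(0.05, 0.05)  # +/- log(19)
#' @export
wald_boundaries <- function(alpha, beta) {
  alpha <- check_number(alpha, "alpha", lower = 0, upper = 1,
                        open_lower = TRUE, open_upper = TRUE)
  beta <- check_number(beta, "beta", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  lower <- log(beta / (1 - alpha))
  upper <- log((1 - beta) / alpha)
  if (lower >= 0 || upper <= 0)
    stop("degenerate boundaries: need alpha + beta < 1 so that lower < 0 < upper",
         call. = FALSE)
  structure(list(alpha = alpha, beta = beta, lower = lower, upper = upper),
            class = "sprt_boundaries")
}

#' @export
print.sprt_boundaries <- function(x, ...) {
  cat(sprintf("Wald SPRT boundaries (alpha = %g, beta = %g): lower %.4f, upper %.4f\n",
              x$alpha, x$beta, x$lower, x$upper))
  invisible(x)
}

#' Log-likelihood-ratio increment for a binary outcome
#'
#' Contribution of one Bernoulli outcome to the H2-over-H1 log-likelihood
#' ratio: `x * log(p2/p1) + (1 - x) * log((1-p2)/(1-p1))`.
#'
#' @param x binary outcome(s), 0 or 1 (vectorized).
#' @param p1 response rate under H1, in (0, 1).
#' @param p2 response rate under H2, in (0, 1).
#' @return numeric increment(s).
#' @export
binomial_llr_increment <- function(x, p1, p2) {
  p1 <- check_number(p1, "p1", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  p2 <- check_number(p2, "p2", lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  if (!all(x %in% c(0, 1))) stop("outcomes must be 0 or 1", call. = FALSE)
  x * log(p2 / p1) + (1 - x) * log((1 - p2) / (1 - p1))
}

#' Truncated SPRT over a stream of binary outcomes
#'
#' Accumulates binomial log-likelihood-ratio increments and stops when a Wald
#' boundary is crossed, or - if `max_n` outcomes are consumed without a
#' crossing - renders a forced decision: by the sign of the cumulative LLR
#' (`forced = "sign"`, H2 iff the LLR is positive) or by proximity to the
#' nearer boundary (`forced = "nearest"`). Truncation keeps an inconclusive
#' sequential study from running forever.
#'
#' @param outcomes either a 0/1 vector of length >= `max_n`, or a function
#'   `f(i)` returning the i-th outcome on demand (lazy stream).
#' @param p1,p2 hypothesized response rates, `p1 < p2`, both in (0, 1).
#' @param alpha,beta error rates defining the Wald boundaries.
#' @param max_n truncation limit (positive integer).
#' @param forced forced-decision rule at truncation.
#' @return object of class `sprt_state`: `decision` (`"accept_H1"` or
#'   `"accept_H2"`), `n` (outcomes consumed), `llr` (final value),
#'   `llr_path`, `boundaries`, `forced_call` (logical).
#' @export
run_truncated_sprt <- function(outcomes, p1, p2, alpha = 0.05, beta = 0.05,
                               max_n = 100L, forced = c("sign", "nearest")) {
  forced <- match.arg(forced)
  if (p1 >= p2) stop("need p1 < p2", call. = FALSE)
  bd <- wald_boundaries(alpha, beta)
  max_n <- check_number(max_n, "max_n", lower = 1, integer = TRUE)
  draw <- if (is.function(outcomes)) {
    outcomes
  } else {
    if (length(outcomes) < max_n)
      stop(sprintf("outcome stream exhausted: %d outcomes supplied, max_n = %d",
                   length(outcomes), max_n), call. = FALSE)
    function(i) outcomes[[i]]
  }
  llr <- 0
  path <- numeric(max_n)
  for (i in seq_len(max_n)) {
    llr <- llr + binomial_llr_increment(draw(i), p1, p2)
    path[i] <- llr
    if (llr >= bd$upper || llr <= bd$lower) {
      return(structure(list(
        decision = if (llr >= bd$upper) "accept_H2" else "accept_H1",
        n = i, llr = llr, llr_path = path[seq_len(i)], boundaries = bd,
        max_n = max_n, forced_call = FALSE), class = "sprt_state"))
    }
  }
  accept2 <- switch(forced,
    sign = llr > 0,
    nearest = (bd$upper - llr) < (llr - bd$lower))
  structure(list(decision = if (accept2) "accept_H2" else "accept_H1",
                 n = max_n, llr = llr, llr_path = path, boundaries = bd,
                 max_n = max_n, forced_call = TRUE),
            class = "sprt_state")
}

#' @export
print.sprt_state <- function(x, ...) {
  cat(sprintf("Truncated SPRT: %s at n = %d (llr = %.3f%s)\n", x$decision,
              x$n, x$llr, if (x$forced_call) ", forced at truncation" else ""))
  invisible(x)
}

#' Sequentially aggregated personalized trials: response-rate SPRT
#'
#' Simulates the two-stage procedure for population-level efficacy claims
#' from individually analyzed N-of-1 trials. Individuals enter one at a time;
#' each undergoes a crossover trial (default 2 arms x 4 periods x 50
#' measures, no washouts, no randomization) in which a responder (probability
#' `true_responder_fraction`) carries an arm-A effect of `responder_effect`
#' marginal-sd units and a non-responder carries none. The within-trial
#' effect test (GLS by default) scores the individual as a "response" when
#' its two-sided p-value is below `per_trial_alpha`, and the resulting binary
#' stream feeds a truncated SPRT of H1: rate = `p1` vs H2: rate = `p2`,
#' truncated at `max_trials` individuals.
#'
#' Within-trial measurement noise is serially uncorrelated unit-variance
#' Gaussian; the within-trial test's own operating characteristics (power,
#' level) therefore set how the observed response stream relates to the true
#' responder fraction. If `per_trial_alpha` is not well below `p1`, false
#' within-trial positives alone push the observed rate toward `p2`.
#'
#' @param true_responder_fraction true responder probability (vectorized: one
#'   summary row per value).
#' @param p1,p2 hypothesized response rates, `p1 < p2`.
#' @param per_trial_alpha significance level of the within-trial test.
#' @param reps simulation replicates per grid value.
#' @param max_trials truncation limit on the number of individuals.
#' @param alpha,beta error rates of the aggregate SPRT.
#' @param responder_effect arm-A effect size in responders (sd units).
#' @param design within-trial crossover design (a [design_spec()]; its
#'   `effect` field is overridden per individual).
#' @param test within-trial test: `"gls"` (default) or `"ols"` (equivalent
#'   here since no serial correlation is simulated, and much faster).
#' @param forced forced-decision rule at truncation (see
#'   [run_truncated_sprt()]).
#' @param seed optional seed.
#' @return data frame with one row per `true_responder_fraction` value:
#'   `true_rate`, `accept_h2` (fraction of replicates accepting H2),
#'   `mean_trials`, `sd_trials`, `reps`.
#' @export
simulate_aggregated <- function(true_responder_fraction, p1 = 0.1, p2 = 0.2,
                                per_trial_alpha = 0.05, reps = 100L,
                                max_trials = 100L, alpha = 0.05, beta = 0.05,
                                responder_effect = 0.3,
                                design = design_spec(periods = 4L, measures = 50L),
                                test = c("gls", "ols"),
                                forced = c("sign", "nearest"), seed = NULL) {
  test <- match.arg(test)
  forced <- match.arg(forced)
  stopifnot(all(true_responder_fraction >= 0), all(true_responder_fraction <= 1))
  reps <- check_number(reps, "reps", lower = 1, integer = TRUE)
  span <- required_span(design)
  with_seed(seed, {
    rows <- lapply(true_responder_fraction, function(f) {
      acc2 <- 0L
      ns <- integer(reps)
      for (r in seq_len(reps)) {
        one_trial <- function(i) {
          responder <- stats::runif(1) < f
          d <- design
          d$effect <- if (responder) responder_effect else 0
          x <- simulate_ar1(span, phi = 0)
          tr <- assemble_trial(x, d, start = 1L)
          res <- if (test == "gls") gls_ar1_test(tr) else ols_dummy_test(tr)
          as.integer(res$p_value < per_trial_alpha)
        }
        st <- run_truncated_sprt(one_trial, p1, p2, alpha, beta,
                                 max_n = max_trials, forced = forced)
        acc2 <- acc2 + (st$decision == "accept_H2")
        ns[r] <- st$n
      }
      data.frame(true_rate = f, accept_h2 = acc2 / reps,
                 mean_trials = mean(ns), sd_trials = stats::sd(ns),
                 reps = reps)
    })
    do.call(rbind, rows)
  })
}
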