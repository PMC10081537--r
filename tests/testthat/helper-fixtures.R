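# shared fixture builders (all fixtures are generated in code)

# minimal trial data frame without going through assemble_trial()
make_trial <- function(values, dummy, time = seq_along(values)) {
  structure(data.frame(time = time, value = values,
                       arm = ifelse(dummy == 1L, "B", "A"),
                       dummy = as.integer(dummy)),
            class = c("nof1_trial", "data.frame"))
}

# constrained-fit object with explicitly chosen parameters
make_cfit <- function(slope, intercept, sigma) {
  structure(list(slope = slope, intercept = intercept, sigma = sigma),
            class = "nof1_cfit")
}

# sample lag-k autocorrelation
sample_acf <- function(x, k) {
  x <- x - mean(x)
  sum(x[-seq_len(k)] * x[seq_len(length(x) - k)]) / sum(x^2)
}

# exact binomial 95% CI bounds for a printed proportion observed at `n` reps
binom_ci95 <- function(p, n = 100L) {
  stats::binom.test(round(p * n), n)$conf.int
}
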