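# internal helpers shared across modules

# Run `expr` under a temporarily seeded RNG stream, restoring the caller's
# stream afterwards so seeded simulations do not perturb outer code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# scalar checks used by the public constructors
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (integer && x != floor(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  below <- if (open_lower) x <= lower else x < lower
  above <- if (open_upper) x >= upper else x > upper
  if (below || above)
    stop(sprintf("`%s` = %g is outside its admissible range %s%g, %g%s", name, x,
                 if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]"), call. = FALSE)
  if (integer) as.integer(x) else x
}

# lag-1 sample autocorrelation (used for residual diagnostics)
lag1_autocor <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  x <- x - mean(x)
  s <- sum(x^2)
  if (s == 0) return(NA_real_)
  sum(x[-1L] * x[-n]) / s
}
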