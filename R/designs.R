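#' Specify a two-arm crossover design
#'
#' A personalized (N-of-1) crossover design with two interventions "A" and
#' "B": `periods` treatment periods per arm, `measures` response measurements
#' per period, optional washout intervals of `washout` measurement-time units
#' between consecutive treatment periods (no response is recorded during a
#' washout, so those series positions are consumed but excluded from
#' analysis), optional randomization of the period order, and an additive
#' intervention effect of `effect` marginal-standard-deviation units applied
#' to every arm-A measurement relative to arm B.
#'
#' @param periods treatment periods per arm (positive integer).
#' @param measures measurements per period (positive integer).
#' @param washout washout length in measurement-time units (>= 0; 0 = none).
#'   Washouts are placed only *between* treatment periods, never at the ends.
#' @param randomize if `TRUE` the order of the `2 * periods` treatment
#'   periods is a uniform random permutation; otherwise strict alternation
#'   starting with A.
#' @param effect additive shift applied to arm-A measurements (real, in
#'   marginal-sd units).
#' @return an object of class `nof1_design`.
#' @examples
#' design_spec(periods = 4, measures = 50, washout = 50)
#' @export
design_spec <- function(periods = 4L, measures = 50L, washout = 0L,
                        randomize = FALSE, effect = 0) {
  spec <- list(
    periods = check_number(periods, "periods", lower = 1, integer = TRUE),
    measures = check_number(measures, "measures", lower = 1, integer = TRUE),
    washout = check_number(washout, "washout", lower = 0, integer = TRUE),
    randomize = isTRUE(randomize),
    effect = check_number(effect, "effect")
  )
  structure(spec, class = "nof1_design")
}

#' @export
print.nof1_design <- function(x, ...) {
  cat(sprintf("2 x %d x %d crossover design (%d analyzed measurements)\n",
              x$periods, x$measures, 2L * x$periods * x$measures))
  cat(sprintf("  washout: %d measure(s)%s | order: %s | effect on A: %+.3g\n",
              x$washout, if (x$washout > 0) " between periods" else "",
              if (x$randomize) "randomized" else "alternating (A first)",
              x$effect))
  invisible(x)
}

#' Total series span a design consumes
#'
#' Number of consecutive series positions needed to carve one trial:
#' `2 * periods * measures` analyzed measurements plus
#' `(2 * periods - 1) * washout` skipped washout positions.
#'
#' @param spec a [design_spec()].
#' @return integer span.
#' @export
required_span <- function(spec) {
  stopifnot(inherits(spec, "nof1_design"))
  2L * spec$periods * spec$measures + (2L * spec$periods - 1L) * spec$washout
}

#' Build the period sequence of a crossover design
#'
#' Lays out the treatment periods (and interleaved washouts, when
#' `spec$washout > 0`) in time order. Without randomization the order is
#' strict alternation starting with A, e.g. `"AWBWAWBWAWBWAWB"` for four
#' periods per arm with washouts; with randomization the multiset of
#' `2 * periods` A/B labels is uniformly permuted (e.g. `"AWAWBWAWBWBWBWA"`).
#'
#' @param spec a [design_spec()].
#' @param seed optional seed for the random permutation.
#' @return data frame with columns `label` (`"A"`, `"B"` or `"W"`) and
#'   `duration` (measurement units), one row per period, classed
#'   `nof1_sequence`.
#' @seealso [sequence_string()] for the compact label string.
#' @export
build_sequence <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "nof1_design"))
  labels <- rep(c("A", "B"), spec$periods)
  if (spec$randomize) labels <- with_seed(seed, sample(labels))
  if (spec$washout > 0L) {
    k <- length(labels)
    lab <- character(2L * k - 1L)
    lab[seq(1L, 2L * k - 1L, by = 2L)] <- labels
    lab[seq(2L, 2L * k - 2L, by = 2L)] <- "W"
    dur <- ifelse(lab == "W", spec$washout, spec$measures)
  } else {
    lab <- labels
    dur <- rep(spec$measures, length(labels))
  }
  structure(data.frame(label = lab, duration = as.integer(dur)),
            class = c("nof1_sequence", "data.frame"))
}

#' @rdname build_sequence
#' @param sequence an object returned by [build_sequence()].
#' @export
sequence_string <- function(sequence) {
  stopifnot(inherits(sequence, "nof1_sequence"))
  paste(sequence$label, collapse = "")
}

#' Carve a personalized trial from a simulated series
#'
#' Chooses a start position uniformly among the positions where the whole
#' design (treatment periods plus washouts) fits inside the series, walks the
#' period sequence assigning consecutive series values to periods, drops the
#' washout stretches (their values are consumed but not analyzed), and adds
#' `spec$effect` to every arm-A measurement. The returned `time` column keeps
#' the original series positions, so washout gaps remain visible to
#' gap-aware analyses.
#'
#' @param series numeric series (e.g. from [simulate_ar1()]).
#' @param spec a [design_spec()].
#' @param seed optional seed governing both the period-order randomization
#'   (if any) and the start position.
#' @param start optional fixed start position (overrides the random draw).
#' @return data frame with columns `time` (original series index), `value`,
#'   `arm` (`"A"`/`"B"`) and `dummy` (0 for A, 1 for B), classed
#'   `nof1_trial`; `2 * periods * measures` rows in increasing time order.
#' @export
assemble_trial <- function(series, spec, seed = NULL, start = NULL) {
  stopifnot(inherits(spec, "nof1_design"))
  span <- required_span(spec)
  if (length(series) < span)
    stop(sprintf("series of length %d cannot hold this design: %d positions required",
                 length(series), span), call. = FALSE)
  with_seed(seed, {
    sq <- build_sequence(spec)
    if (is.null(start)) {
      start <- sample.int(length(series) - span + 1L, 1L)
    } else {
      start <- check_number(start, "start", lower = 1,
                            upper = length(series) - span + 1L, integer = TRUE)
    }
    pos <- start
    keep_time <- integer(0)
    arm <- character(0)
    for (i in seq_len(nrow(sq))) {
      idx <- pos:(pos + sq$duration[i] - 1L)
      if (sq$label[i] != "W") {
        keep_time <- c(keep_time, idx)
        arm <- c(arm, rep(sq$label[i], length(idx)))
      }
      pos <- pos + sq$duration[i]
    }
    value <- series[keep_time] + ifelse(arm == "A", spec$effect, 0)
    structure(data.frame(time = keep_time, value = value, arm = arm,
                         dummy = as.integer(arm == "B")),
              class = c("nof1_trial", "data.frame"))
  })
}

#' Write / read trial data as CSV
#'
#' Plain-text interchange for labeled trial measurements: header
#' `time,value,arm,dummy`.
#'
#' @param trial a `nof1_trial` data frame.
#' @param path file path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns a `nof1_trial` data frame.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "nof1_trial"))
  utils::write.csv(as.data.frame(trial)[c("time", "value", "arm", "dummy")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c(arm = "character"))
  need <- c("time", "value", "arm", "dummy")
  if (!all(need %in% names(d)))
    stop("trial CSV must have columns time,value,arm,dummy", call. = FALSE)
  d <- d[order(d$time), need]
  rownames(d) <- NULL
  structure(d, class = c("nof1_trial", "data.frame"))
}
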