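#' Tolerance specification
#'
#' Bundles the two constants of a one-sided tolerance statement: the
#' proportion of the population allowed in the deficit tail and the
#' confidence with which that proportion is bounded. The defaults give the
#' conventional 95%/95% statement (at most 5% of the population beyond the
#' limit, asserted with 95% confidence) used throughout the Equivalent
#' Score literature.
#'
#' @param coverage_tail Proportion of the population in the deficit tail.
#'   Must lie strictly between 0 and 0.5. Default 0.05.
#' @param confidence Confidence level of the tolerance statement. Must lie
#'   strictly between 0.5 and 1. Default 0.95.
#' @return An object of class `"tolerance_spec"`.
#' @examples
#' tolerance_spec()
#' tolerance_spec(coverage_tail = 0.1, confidence = 0.9)
#' @export
tolerance_spec <- function(coverage_tail = 0.05, confidence = 0.95) {
  if (!is.numeric(coverage_tail) || length(coverage_tail) != 1L ||
      !is.finite(coverage_tail) || coverage_tail <= 0 || coverage_tail >= 0.5) {
    stop("'coverage_tail' must be a single number strictly between 0 and 0.5",
         call. = FALSE)
  }
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      !is.finite(confidence) || confidence <= 0.5 || confidence >= 1) {
    stop("'confidence' must be a single number strictly between 0.5 and 1",
         call. = FALSE)
  }
  structure(list(coverage_tail = coverage_tail, confidence = confidence),
            class = "tolerance_spec")
}

#' @export
print.tolerance_spec <- function(x, ...) {
  cat(sprintf("One-sided tolerance specification: %g%% tail coverage, %g%% confidence\n",
              100 * x$coverage_tail, 100 * x$confidence))
  invisible(x)
}

as_tolerance_spec <- function(spec) {
  if (inherits(spec, "tolerance_spec")) return(spec)
  if (is.list(spec) && all(c("coverage_tail", "confidence") %in% names(spec))) {
    return(tolerance_spec(spec$coverage_tail, spec$confidence))
  }
  stop("'spec' must be a tolerance_spec object", call. = FALSE)
}

#' Normative sample of adjusted test scores
#'
#' The container all norming starts from: a vector of adjusted scores and
#' the scoring direction of the test. For accuracy-like tests (recall,
#' naming) higher scores are better and the deficit tail is the low end;
#' for timed tests (execution or reaction time) lower scores are better and
#' the deficit tail is the high end.
#'
#' @param scores Numeric vector of adjusted test scores; all values must be
#'   finite.
#' @param direction `"higher_better"` (deficit tail = low scores) or
#'   `"lower_better"` (deficit tail = high scores).
#' @return An object of class `"normative_sample"` with elements `scores`,
#'   `direction` and `n`.
#' @examples
#' normative_sample(rnorm(300, 50, 10), direction = "higher_better")
#' @export
normative_sample <- function(scores, direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (!is.numeric(scores) || length(scores) == 0L) {
    stop("'scores' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    bad <- which(!is.finite(scores))
    stop(sprintf("all scores must be finite; offending position(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  structure(list(scores = as.numeric(scores), direction = direction,
                 n = length(scores)),
            class = "normative_sample")
}

#' @export
print.normative_sample <- function(x, ...) {
  cat(sprintf("Normative sample: n = %d, direction = %s\n", x$n, x$direction))
  cat(sprintf("  score range: [%.4g, %.4g], median %.4g\n",
              min(x$scores), max(x$scores), stats::median(x$scores)))
  invisible(x)
}

# Scores ordered from the deficit tail: ascending when low scores are worse,
# descending when high scores are worse. Element k is the k-th worst score.
deficit_sorted <- function(sample) {
  sort(sample$scores, decreasing = sample$direction == "lower_better")
}

# Signed transform under which "worse" is always "smaller". Used for all
# direction-aware comparisons.
worseness <- function(x, direction) {
  if (direction == "lower_better") -x else x
}

#' Convert a deficit-tail rank to an ascending-score position
#'
#' Ranks in this package are 1-based and counted from the deficit tail. For
#' reporting against conventions that count from the low-score end
#' regardless of direction, this converts a deficit-tail rank to its
#' position in ascending score order (e.g. for a timed test with n = 300,
#' the 9th worst observation is the 292nd in ascending order).
#'
#' @param rank 1-based rank(s) from the deficit tail.
#' @param n Sample size.
#' @param direction Scoring direction of the test.
#' @return Integer position(s) in ascending score order.
#' @export
ascending_position <- function(rank, n, direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (direction == "lower_better") n + 1L - as.integer(rank) else as.integer(rank)
}
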