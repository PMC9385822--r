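#' Outer tolerance limit rank
#'
#' Rank (1-based, counted from the deficit tail) of the order statistic
#' that bounds the deficit tail from outside: with confidence `confidence`,
#' no more than a fraction `coverage_tail` of the population scores worse
#' than the k-th worst observation. The rank is the largest k such that
#' `pbinom(k - 1, n, coverage_tail) <= 1 - confidence`.
#'
#' At the 95%/95% defaults the rule has no solution below n = 59 (the
#' sample minimum itself is not a valid limit), and an error is raised
#' rather than clamping.
#'
#' @param n Sample size.
#' @param spec A [tolerance_spec()].
#' @return Integer rank k >= 1; the k-th worst observation is the OTL.
#' @examples
#' otl_rank(300) # 9
#' otl_rank(1000) # 39
#' @export
otl_rank <- function(n, spec = tolerance_spec()) {
  spec <- as_tolerance_spec(spec)
  n <- check_n(n)
  alpha <- 1 - spec$confidence
  # pbinom(k - 1, n, p) is increasing in k, so the feasible k form 1..k_max
  if (stats::pbinom(0, n, spec$coverage_tail) > alpha) {
    stop(sprintf(
      "sample too small for outer tolerance limit: n = %d, minimum n = %d at %g%%/%g%%",
      n, min_n_for_otl(spec), 100 * spec$coverage_tail, 100 * spec$confidence),
      call. = FALSE)
  }
  k <- 1L
  while (k < n && stats::pbinom(k, n, spec$coverage_tail) <= alpha) k <- k + 1L
  k
}

#' Inner tolerance limit rank
#'
#' Rank (1-based, from the deficit tail) of the order statistic bounding
#' the deficit tail from inside: with confidence `confidence`, no less than
#' a fraction `coverage_tail` of the population scores worse than the k-th
#' worst observation. The rank is the smallest k such that
#' `pbinom(k, n, coverage_tail) >= confidence`. Scores falling between the
#' OTL and the ITL are of uncertain classification.
#'
#' @inheritParams otl_rank
#' @return Integer rank k >= `otl_rank(n, spec)`.
#' @examples
#' itl_rank(300) # 21
#' itl_rank(1000) # 62
#' @export
itl_rank <- function(n, spec = tolerance_spec()) {
  spec <- as_tolerance_spec(spec)
  n <- check_n(n)
  if (stats::pbinom(0, n, spec$coverage_tail) > 1 - spec$confidence) {
    stop(sprintf(
      "sample too small for tolerance limits: n = %d, minimum n = %d at %g%%/%g%%",
      n, min_n_for_otl(spec), 100 * spec$coverage_tail, 100 * spec$confidence),
      call. = FALSE)
  }
  k <- 1L
  while (k <= n && stats::pbinom(k, n, spec$coverage_tail) < spec$confidence) k <- k + 1L
  k
}

#' Minimum sample size admitting an outer tolerance limit
#'
#' Smallest n for which `(1 - coverage_tail)^n <= 1 - confidence`, i.e. for
#' which even the worst observation qualifies as an OTL. 59 at the
#' 95%/95% defaults.
#'
#' @param spec A [tolerance_spec()].
#' @return Integer minimum sample size.
#' @export
min_n_for_otl <- function(spec = tolerance_spec()) {
  spec <- as_tolerance_spec(spec)
  as.integer(ceiling(log(1 - spec$confidence) / log(1 - spec$coverage_tail)))
}

check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n)) {
    stop("'n' must be a single positive integer", call. = FALSE)
  }
  as.integer(n)
}

#' Non-parametric tolerance limits of a normative sample
#'
#' Computes the OTL and ITL ranks for the sample size and extracts the
#' corresponding order-statistic scores, counting from the deficit tail
#' (ascending scores when lower scores are worse... i.e. for timed tests
#' the ranks count down from the high end).
#'
#' @param sample A [normative_sample()].
#' @param spec A [tolerance_spec()].
#' @return A list of class `"np_tl"` with `otl_rank`, `itl_rank`,
#'   `otl_score`, `itl_score`, plus the sample size and direction.
#' @examples
#' s <- normative_sample(rnorm(300, 50, 10), "higher_better")
#' np_tolerance_limits(s)
#' @export
np_tolerance_limits <- function(sample, spec = tolerance_spec()) {
  stopifnot(inherits(sample, "normative_sample"))
  spec <- as_tolerance_spec(spec)
  ord <- deficit_sorted(sample)
  ko <- otl_rank(sample$n, spec)
  ki <- itl_rank(sample$n, spec)
  structure(list(otl_rank = ko, itl_rank = ki,
                 otl_score = ord[ko], itl_score = ord[ki],
                 n = sample$n, direction = sample$direction, spec = spec),
            class = "np_tl")
}

#' @export
print.np_tl <- function(x, ...) {
  cat(sprintf("Non-parametric tolerance limits (n = %d, %s):\n", x$n, x$direction))
  cat(sprintf("  OTL: rank %d from the deficit tail, score %.4g\n",
              x$otl_rank, x$otl_score))
  cat(sprintf("  ITL: rank %d from the deficit tail, score %.4g\n",
              x$itl_rank, x$itl_score))
  invisible(x)
}

#' Parametric one-sided normal tolerance limit
#'
#' The normal-theory counterpart of the non-parametric OTL: mean - k * sd
#' (or mean + k * sd when the deficit tail is the high end), where the
#' k-factor covers `1 - coverage_tail` of a normal population with the
#' stated confidence. k is the noncentral-t quantile
#' `qt(confidence, df = n - 1, ncp = qnorm(1 - coverage_tail) * sqrt(n)) / sqrt(n)`;
#' as n grows it tends to the standard-normal quantile (1.6449 at defaults).
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (n - 1 denominator).
#' @param n Sample size, at least 2.
#' @param spec A [tolerance_spec()].
#' @param direction Which side the deficit tail is on.
#' @return The tolerance limit score, strictly on the deficit side of the
#'   mean.
#' @examples
#' parametric_lower_tl(50, 10, 300)
#' @export
parametric_lower_tl <- function(mean, sd, n,
                                spec = tolerance_spec(),
                                direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  spec <- as_tolerance_spec(spec)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2) {
    stop("'n' must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop("'sd' must be a single positive number", call. = FALSE)
  }
  k <- tl_k_factor(n, spec)
  if (direction == "lower_better") mean + k * sd else mean - k * sd
}

# One-sided normal tolerance k-factor (content 1 - coverage_tail,
# confidence level spec$confidence).
tl_k_factor <- function(n, spec = tolerance_spec()) {
  spec <- as_tolerance_spec(spec)
  delta <- stats::qnorm(1 - spec$coverage_tail) * sqrt(n)
  # qt warns about reduced precision at large ncp; the attained accuracy
  # (~1e-8) is far below any score resolution
  suppressWarnings(stats::qt(spec$confidence, df = n - 1, ncp = delta)) / sqrt(n)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] returning the W statistic
#' and p-value; used to decide whether a normative distribution can be
#' treated as Gaussian (it typically cannot for timed or ceiling-affected
#' tests).
#'
#' @param scores Numeric vector, 3 to 5000 finite values.
#' @return A list of class `"normality_result"` with `W` and `p_value`.
#' @export
normality_test <- function(scores) {
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop("'scores' must be a numeric vector of finite values", call. = FALSE)
  }
  if (length(scores) < 3L || length(scores) > 5000L) {
    stop("Shapiro-Wilk test requires between 3 and 5000 observations",
         call. = FALSE)
  }
  sw <- stats::shapiro.test(scores)
  structure(list(W = unname(sw$statistic), p_value = sw$p.value),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk: W = %.4f, p %s\n", x$W,
              if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value)))
  invisible(x)
}
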