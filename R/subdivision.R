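#' Rank of the median observation
#'
#' 1-based rank of the observation taken as the ES3/ES4 boundary, counted
#' from the low-score end: `ceiling((n + 1) / 2)`. For even n this selects
#' the upper middle observation (151 for n = 300, 501 for n = 1000). When
#' the deficit tail is the high end the same observation sits at rank
#' `n + 1 - ceiling((n + 1) / 2)` from the deficit tail; [build_norms()]
#' performs that conversion.
#'
#' @param n Sample size.
#' @return Integer rank.
#' @examples
#' median_rank(300) # 151
#' median_rank(100) # 51
#' @export
median_rank <- function(n) {
  n <- check_n(n)
  as.integer(ceiling((n + 1) / 2))
}

# Rank of the median observation counted from the deficit tail. Identical
# to median_rank(n) for odd n or when the deficit tail is the low end; for
# even n with a high-end deficit tail the median observation is one rank
# nearer the tail (n = 300: 150th worst rather than 151st).
deficit_median_rank <- function(n, direction) {
  m <- median_rank(n)
  if (direction == "lower_better") n + 1L - m else m
}

#' Equal-thirds rank subdivision between the OTL and the median
#'
#' Splits the rank interval between the outer tolerance limit and the
#' median into three blocks of equal rank count: with
#' `step = floor((median_rank - otl_rank) / 3)`, the ES1/ES2 boundary is
#' `otl_rank + step` and the ES2/ES3 boundary `otl_rank + 2 * step`. Any
#' remainder from the integer division accrues to the block adjoining the
#' median.
#'
#' @param otl_rank OTL rank from the deficit tail.
#' @param median_rank Median rank from the deficit tail.
#' @return Integer vector `c(c1, c2)` of the ES1/ES2 and ES2/ES3 boundary
#'   ranks.
#' @examples
#' rank_cutoffs(9, 151) # 56 103
#' rank_cutoffs(39, 501) # 193 347
#' @export
rank_cutoffs <- function(otl_rank, median_rank) {
  otl_rank <- check_n(otl_rank)
  median_rank <- check_n(median_rank)
  if (median_rank <= otl_rank) {
    stop("invalid norms: median rank must exceed the OTL rank", call. = FALSE)
  }
  step <- (median_rank - otl_rank) %/% 3L
  c(otl_rank + step, otl_rank + 2L * step)
}

#' z-score subdivision of the interval between the OTL and the mean
#'
#' The classical parametric rule for the intermediate ES boundaries: the
#' standardized interval from the observed OTL score to the sample mean
#' (z = 0) is cut into three equal z-width parts. Equivalently, on the
#' score scale, b1 = mean + (2/3)(otl - mean) and b2 = mean + (1/3)(otl -
#' mean). The standard deviation enters only through the standardization
#' and cancels from the boundary scores, but is validated here because a
#' degenerate sd invalidates the z-scale.
#'
#' @param mean Sample mean of the adjusted scores.
#' @param sd Sample standard deviation (n - 1 denominator), positive.
#' @param otl_score Observed OTL score, on the deficit side of the mean.
#' @return Numeric `c(b1, b2)`: the ES1/ES2 and ES2/ES3 boundary scores,
#'   ordered from the deficit side.
#' @examples
#' zscore_cutoffs(0, 1, -1.763)
#' @export
zscore_cutoffs <- function(mean, sd, otl_score) {
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop("'sd' must be a single positive number", call. = FALSE)
  }
  stopifnot(is.numeric(mean), is.finite(mean), is.numeric(otl_score),
            is.finite(otl_score))
  c(mean + 2 / 3 * (otl_score - mean), mean + 1 / 3 * (otl_score - mean))
}

#' Direct trisection of the score interval between the OTL and the median
#'
#' The simplest rule for the intermediate ES boundaries: cut the raw score
#' interval between the OTL score and the median score into three
#' equal-width parts and take the two interior points, ordered from the
#' deficit side.
#'
#' @param otl_score Observed OTL score.
#' @param median_score Median score; must differ from `otl_score`.
#' @return Numeric `c(b1, b2)` ordered from the deficit side.
#' @examples
#' direct_cutoffs(6.79, 38.21) # 17.26 27.73 (to 2 decimals)
#' direct_cutoffs(72.86, 42.35) # 62.69 52.52
#' @export
direct_cutoffs <- function(otl_score, median_score) {
  stopifnot(is.numeric(otl_score), is.finite(otl_score),
            is.numeric(median_score), is.finite(median_score))
  if (otl_score == median_score) {
    stop("invalid norms: OTL score and median score coincide", call. = FALSE)
  }
  span <- median_score - otl_score
  c(otl_score + span / 3, otl_score + 2 * span / 3)
}

#' Nearest observation rank to a target score
#'
#' Rank (from the deficit tail) of the observation whose score is closest
#' to `target_score`. Ties in score distance break toward the median — the
#' less pathological rank — which is conservative against over-diagnosis;
#' set `tie = "deficit"` for the opposite convention.
#'
#' @param sample A [normative_sample()].
#' @param target_score Score to locate.
#' @param tie Tie-breaking rule: `"median"` (default) or `"deficit"`.
#' @return Integer rank from the deficit tail.
#' @export
nearest_rank <- function(sample, target_score, tie = c("median", "deficit")) {
  tie <- match.arg(tie)
  stopifnot(inherits(sample, "normative_sample"),
            is.numeric(target_score), is.finite(target_score))
  ord <- deficit_sorted(sample)
  d <- abs(ord - target_score)
  cand <- which(d == min(d))
  if (length(cand) == 1L) return(cand)
  m <- deficit_median_rank(sample$n, sample$direction)
  if (tie == "median") cand[which.min(abs(cand - m))] else min(cand)
}

#' Build Equivalent Score norms from a normative sample
#'
#' Constructs the four boundary scores delimiting ES0..ES4. The two fixed
#' endpoints are method-independent: b0 is the order statistic at the OTL
#' rank and b3 the median observation. The two interior boundaries (b1 =
#' ES1/ES2, b2 = ES2/ES3) come from the chosen method:
#' \describe{
#'   \item{rank}{order statistics at the equal-thirds rank cutoffs
#'     ([rank_cutoffs()]); distribution-free, equal category density.}
#'   \item{zscore}{equal thirds on the standardized scale between the OTL
#'     score and the sample mean ([zscore_cutoffs()]).}
#'   \item{direct}{arithmetic trisection of the score interval between the
#'     OTL score and the median score ([direct_cutoffs()]).}
#' }
#' For the score-based methods the boundary ranks reported in
#' `rank_limits` are the nearest observation ranks ([nearest_rank()]).
#'
#' @param sample A [normative_sample()].
#' @param method `"rank"`, `"zscore"` or `"direct"`.
#' @param spec A [tolerance_spec()].
#' @return An object of class `"es_norms"`: `method`, `direction`, `n`,
#'   `spec`, `boundary_scores` (named b0..b3, ordered from the deficit
#'   tail), `itl_score`, and `rank_limits` (otl, itl, c1, c2, median; all
#'   1-based from the deficit tail).
#' @examples
#' s <- normative_sample(rnorm(300, 50, 10), "higher_better")
#' build_norms(s, method = "rank")
#' @export
build_norms <- function(sample, method = c("rank", "zscore", "direct"),
                        spec = tolerance_spec()) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "normative_sample"))
  spec <- as_tolerance_spec(spec)
  ord <- deficit_sorted(sample)
  n <- sample$n
  ko <- otl_rank(n, spec)
  ki <- itl_rank(n, spec)
  m <- deficit_median_rank(n, sample$direction)
  if (m <= ko) {
    stop("invalid norms: median rank does not exceed the OTL rank", call. = FALSE)
  }
  b0 <- ord[ko]
  b3 <- ord[m]
  if (method == "rank") {
    cc <- rank_cutoffs(ko, m)
    c1 <- cc[1L]; c2 <- cc[2L]
    b1 <- ord[c1]; b2 <- ord[c2]
  } else {
    if (method == "zscore") {
      mu <- mean(sample$scores)
      sdev <- stats::sd(sample$scores)
      if (worseness(b0, sample$direction) >= worseness(mu, sample$direction)) {
        warning("OTL score is not on the deficit side of the mean; ",
                "z-score subdivision is degenerate", call. = FALSE)
      }
      bb <- zscore_cutoffs(mu, sdev, b0)
    } else {
      bb <- direct_cutoffs(b0, b3)
    }
    b1 <- bb[1L]; b2 <- bb[2L]
    c1 <- nearest_rank(sample, b1)
    c2 <- nearest_rank(sample, b2)
  }
  structure(list(
    method = method,
    direction = sample$direction,
    n = n,
    spec = spec,
    boundary_scores = c(b0 = b0, b1 = b1, b2 = b2, b3 = b3),
    itl_score = ord[ki],
    rank_limits = list(otl = ko, itl = ki, c1 = c1, c2 = c2, median = m)
  ), class = "es_norms")
}

#' @export
print.es_norms <- function(x, ...) {
  cat(sprintf("Equivalent Score norms (%s method, n = %d, %s)\n",
              x$method, x$n, x$direction))
  b <- round(x$boundary_scores, 2)
  cat(sprintf("  boundaries (deficit tail -> median): ES0|%s|ES1|%s|ES2|%s|ES3|%s|ES4\n",
              b[1], b[2], b[3], b[4]))
  rl <- x$rank_limits
  cat(sprintf("  ranks from deficit tail: OTL %d, ITL %d, ES1/2 %d, ES2/3 %d, median %d\n",
              rl$otl, rl$itl, rl$c1, rl$c2, rl$median))
  invisible(x)
}

# Category index 0..4 for each score under the given norms.
# boundary_rule "worse": a score equal to an interior boundary (b0, b1, b2)
# falls in the worse (lower-ES) category. median_rule chooses where a score
# exactly at the median boundary b3 goes: "es4" (scoring default) or "es3"
# (the convention under which category counts equal consecutive rank
# differences, used for density tables).
assign_category <- function(scores, norms,
                            boundary_rule = c("worse", "better"),
                            median_rule = c("es4", "es3")) {
  boundary_rule <- match.arg(boundary_rule)
  median_rule <- match.arg(median_rule)
  t <- worseness(scores, norms$direction)
  tb <- worseness(norms$boundary_scores, norms$direction)
  le <- if (boundary_rule == "worse") `<=` else `<`
  es <- integer(length(t))
  es[!le(t, tb[1L])] <- 1L
  es[!le(t, tb[2L])] <- 2L
  es[!le(t, tb[3L])] <- 3L
  top <- if (median_rule == "es4") t >= tb[4L] else t > tb[4L]
  es[top] <- 4L
  es
}

#' Category density of a sample under built norms
#'
#' Counts the observations falling in each ES category, with boundary
#' observations assigned to the worse category and the median observation
#' counted in ES3 — the convention under which, for a sample with all
#' distinct scores, the ES1..ES3 counts are the consecutive differences of
#' the boundary ranks and the rank method yields (near-)equal densities.
#' Percentages are over the full sample size.
#'
#' @param sample The [normative_sample()] the norms were built from.
#' @param norms An [build_norms()] result.
#' @return A data frame of class `"density_report"` with columns
#'   `category`, `count`, `pct` (rounded to 2 decimals for display).
#' @examples
#' s <- normative_sample(rnorm(1000, 50, 10), "higher_better")
#' density_report(s, build_norms(s, "rank"))
#' @export
density_report <- function(sample, norms) {
  stopifnot(inherits(sample, "normative_sample"), inherits(norms, "es_norms"))
  if (sample$n != norms$n) {
    stop("norms were not built from a sample of this size", call. = FALSE)
  }
  es <- assign_category(sample$scores, norms, median_rule = "es3")
  counts <- tabulate(es + 1L, nbins = 5L)
  out <- data.frame(category = paste0("ES", 0:4),
                    count = counts,
                    pct = round(100 * counts / sample$n, 2))
  class(out) <- c("density_report", "data.frame")
  out
}

#' @export
print.density_report <- function(x, ...) {
  cat("ES category density:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
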