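#' Assign an Equivalent Score to an adjusted score
#'
#' Compares one adjusted score to the boundary scores of built norms and
#' returns the ES category (0-4), its qualitative label, and an
#' uncertainty flag raised when the score lies strictly between the outer
#' and inner tolerance limits — the zone where neither a diagnosis of
#' pathology nor of normality is safe.
#'
#' A score exactly on an interior boundary (b0, b1, b2) falls in the worse
#' category by default (the OTL is read as the limit *of* ES0); a score
#' exactly at the median boundary belongs to ES4. Both conventions are
#' configurable since usage varies.
#'
#' @param score A single finite adjusted score.
#' @param norms An [build_norms()] result.
#' @param boundary_rule `"worse"` (default) or `"better"`: category of a
#'   score exactly equal to an interior boundary.
#' @param median_rule `"es4"` (default) or `"es3"`: category of a score
#'   exactly at the median boundary.
#' @return A list of class `"es_result"`: `es` (integer 0-4), `label`
#'   (defective / borderline / low-end normal / normal), `uncertain`.
#' @examples
#' s <- normative_sample(rnorm(300, 50, 10), "higher_better")
#' nm <- build_norms(s, "rank")
#' assign_es(35, nm)
#' @export
assign_es <- function(score, norms,
                      boundary_rule = c("worse", "better"),
                      median_rule = c("es4", "es3")) {
  if (!is.numeric(score) || length(score) != 1L || !is.finite(score)) {
    stop("'score' must be a single finite number", call. = FALSE)
  }
  stopifnot(inherits(norms, "es_norms"))
  es <- assign_category(score, norms, boundary_rule, median_rule)
  t <- worseness(score, norms$direction)
  res <- list(es = es,
              label = es_label(es),
              uncertain = t > worseness(norms$boundary_scores[["b0"]], norms$direction) &&
                t < worseness(norms$itl_score, norms$direction))
  class(res) <- "es_result"
  res
}

es_label <- function(es) {
  c("defective", "borderline", "low-end normal", "normal", "normal")[es + 1L]
}

#' @export
print.es_result <- function(x, ...) {
  cat(sprintf("ES = %d (%s)%s\n", x$es, x$label,
              if (x$uncertain) " [uncertain: between OTL and ITL]" else ""))
  invisible(x)
}

#' Classify a batch of adjusted scores
#'
#' Elementwise [assign_es()] over a score vector, plus a per-category
#' summary of counts and percentages.
#'
#' @param scores Numeric vector of finite adjusted scores (may be empty).
#' @param norms An [build_norms()] result.
#' @inheritParams assign_es
#' @return A data frame of class `"es_classification"` with columns
#'   `score`, `es`, `label`, `uncertain`; the per-category summary is in
#'   `attr(, "summary")` (a `density_report`-shaped data frame).
#' @examples
#' s <- normative_sample(rnorm(300, 50, 10), "higher_better")
#' nm <- build_norms(s, "rank")
#' cls <- classify_batch(c(20, 35, 50, 70), nm)
#' attr(cls, "summary")
#' @export
classify_batch <- function(scores, norms,
                           boundary_rule = c("worse", "better"),
                           median_rule = c("es4", "es3")) {
  stopifnot(inherits(norms, "es_norms"))
  if (length(scores) > 0 && (!is.numeric(scores) || any(!is.finite(scores)))) {
    stop("'scores' must be numeric and finite", call. = FALSE)
  }
  scores <- as.numeric(scores)
  es <- assign_category(scores, norms, boundary_rule, median_rule)
  t <- worseness(scores, norms$direction)
  unc <- t > worseness(norms$boundary_scores[["b0"]], norms$direction) &
    t < worseness(norms$itl_score, norms$direction)
  out <- data.frame(score = scores,
                    es = es,
                    label = if (length(es)) es_label(es) else character(0),
                    uncertain = unc)
  counts <- tabulate(es + 1L, nbins = 5L)
  attr(out, "summary") <- data.frame(
    category = paste0("ES", 0:4),
    count = counts,
    pct = round(100 * counts / max(1L, length(scores)), 2))
  class(out) <- c("es_classification", "data.frame")
  out
}

#' @export
print.es_classification <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat("\nSummary:\n")
  print.data.frame(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}
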