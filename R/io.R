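#' Write Equivalent Score norms to JSON
#'
#' Serializes an `es_norms` object (method, direction, n, tolerance
#' specification, boundary scores, ITL score, rank limits) with a schema
#' version, so norms built once can be shipped and reused for scoring.
#'
#' @param norms An [build_norms()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_norms <- function(norms, path) {
  stopifnot(inherits(norms, "es_norms"))
  x <- list(schema = "es_norms/1",
            method = norms$method,
            direction = norms$direction,
            n = norms$n,
            spec = list(coverage_tail = norms$spec$coverage_tail,
                        confidence = norms$spec$confidence),
            boundary_scores = as.list(norms$boundary_scores),
            itl_score = norms$itl_score,
            rank_limits = norms$rank_limits)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read Equivalent Score norms from JSON
#'
#' @param path Path to a file written by [write_norms()].
#' @return An `es_norms` object.
#' @export
read_norms <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema) || !identical(x$schema, "es_norms/1")) {
    stop(sprintf("not an es_norms JSON file (schema %s): %s",
                 if (is.null(x$schema)) "missing" else x$schema, path),
         call. = FALSE)
  }
  structure(list(
    method = x$method,
    direction = x$direction,
    n = as.integer(x$n),
    spec = tolerance_spec(x$spec$coverage_tail, x$spec$confidence),
    boundary_scores = unlist(x$boundary_scores)[c("b0", "b1", "b2", "b3")],
    itl_score = x$itl_score,
    rank_limits = lapply(x$rank_limits, as.integer)
  ), class = "es_norms")
}

#' Flatten norms to a single CSV-ready row
#'
#' @param x An `es_norms` object.
#' @param ... Unused.
#' @return A one-row data frame with the method, direction, n, tolerance
#'   constants, boundary scores and rank limits.
#' @export
as.data.frame.es_norms <- function(x, ...) {
  data.frame(method = x$method, direction = x$direction, n = x$n,
             coverage_tail = x$spec$coverage_tail,
             confidence = x$spec$confidence,
             b0 = x$boundary_scores[["b0"]], b1 = x$boundary_scores[["b1"]],
             b2 = x$boundary_scores[["b2"]], b3 = x$boundary_scores[["b3"]],
             itl_score = x$itl_score,
             otl_rank = x$rank_limits$otl, itl_rank = x$rank_limits$itl,
             c1_rank = x$rank_limits$c1, c2_rank = x$rank_limits$c2,
             median_rank = x$rank_limits$median)
}

#' Write a demographic adjustment model to JSON
#'
#' Only named transforms (`identity`, `log`, `sqrt`) survive
#' serialization; models fitted with custom transform functions must be
#' kept in R.
#'
#' @param model A [fit_adjustment()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "demographic_model"))
  if (any(model$transforms == "custom")) {
    stop("models with custom transform functions cannot be serialized",
         call. = FALSE)
  }
  x <- list(schema = "demographic_model/1",
            intercept = model$intercept,
            coefficients = as.list(model$coefficients),
            reference = as.list(model$reference),
            residual_sd = model$residual_sd,
            r_squared = model$r_squared,
            transforms = as.list(model$transforms),
            levels = model$levels)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a demographic adjustment model from JSON
#'
#' @param path Path to a file written by [write_model()].
#' @return A `demographic_model` object.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema) || !identical(x$schema, "demographic_model/1")) {
    stop(sprintf("not a demographic_model JSON file: %s", path), call. = FALSE)
  }
  structure(list(
    intercept = x$intercept,
    coefficients = unlist(x$coefficients),
    reference = unlist(x$reference),
    residual_sd = x$residual_sd,
    r_squared = x$r_squared,
    transforms = unlist(x$transforms),
    levels = lapply(x$levels, as.character)
  ), class = "demographic_model")
}
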