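#' Reference rank table for arbitrary sample sizes
#'
#' Tabulates, for each sample size, the 1-based ranks (from the deficit
#' tail) of the OTL, ITL, the two rank-method intermediate boundaries
#' (ES1/ES2 and ES2/ES3), and the median. Ranks depend only on n, so this
#' table lets norms be read off without any computation on the sample
#' itself. Sizes too small for an outer tolerance limit at the given
#' specification yield NA ranks and an explanatory note.
#'
#' @param sizes Integer vector of sample sizes.
#' @param spec A [tolerance_spec()].
#' @return A data frame with columns `n`, `otl`, `itl`, `es1_es2`,
#'   `es2_es3`, `median`, `note`.
#' @examples
#' reference_table(c(100, 300, 600))
#' @export
reference_table <- function(sizes, spec = tolerance_spec()) {
  spec <- as_tolerance_spec(spec)
  rows <- lapply(sizes, function(n) {
    n <- check_n(n)
    if (n < min_n_for_otl(spec)) {
      return(data.frame(n = n, otl = NA_integer_, itl = NA_integer_,
                        es1_es2 = NA_integer_, es2_es3 = NA_integer_,
                        median = median_rank(n),
                        note = sprintf("sample too small for OTL (minimum n = %d)",
                                       min_n_for_otl(spec))))
    }
    o <- otl_rank(n, spec)
    m <- median_rank(n)
    cc <- rank_cutoffs(o, m)
    data.frame(n = n, otl = o, itl = itl_rank(n, spec),
               es1_es2 = cc[1L], es2_es3 = cc[2L], median = m, note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read scores (and optional covariates) from a CSV file
#'
#' Reads a normative CSV. A file with a single numeric column (or a
#' `score` column and nothing else) becomes a [normative_sample()]; a file
#' with a `score` column plus covariate columns is returned as a validated
#' data frame ready for [fit_adjustment()]. Missing or non-numeric score
#' cells are reported with their row numbers.
#'
#' @param path Path to a CSV file with a header row.
#' @param direction Scoring direction for the sample.
#' @param score_col Name of the score column; defaults to `"score"`, or
#'   the single column of a one-column file.
#' @return A `normative_sample` or, when covariates are present, a data
#'   frame with the score and covariate columns.
#' @export
read_scores <- function(path, direction = c("higher_better", "lower_better"),
                        score_col = "score") {
  direction <- match.arg(direction)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (ncol(df) == 1L) score_col <- names(df)[1L]
  if (!score_col %in% names(df)) {
    stop(sprintf("no '%s' column in %s (columns: %s)", score_col, path,
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  sc <- df[[score_col]]
  if (!is.numeric(sc)) sc <- suppressWarnings(as.numeric(sc))
  bad <- which(!is.finite(sc))
  if (length(bad)) {
    stop(sprintf("missing or non-numeric score(s) at data row(s): %s",
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  df[[score_col]] <- sc
  if (ncol(df) == 1L) {
    normative_sample(sc, direction)
  } else {
    df
  }
}
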