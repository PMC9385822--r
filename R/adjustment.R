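#' Fit a demographic adjustment model
#'
#' Regresses raw test scores on transformed demographic covariates by
#' ordinary least squares, so their estimated contribution can be removed
#' before norming. All declared covariates are kept: no significance-based
#' predictor selection is performed. Transforms default to the identity
#' for numeric covariates; two-level factor or character columns (e.g.
#' sex) are contrast-coded 0/1. Reference values — the sample means of the
#' transformed covariates — are stored so that adjustment is centred on
#' the fitting sample.
#'
#' @param raw_scores Numeric vector of raw scores, no missing values.
#' @param covariates Data frame of demographic columns (e.g. age,
#'   education, sex), same number of rows, no missing values.
#' @param transforms Optional named list mapping covariate names to a
#'   transform: one of `"identity"`, `"log"`, `"sqrt"`, or a function.
#'   Unnamed covariates get the identity.
#' @return An object of class `"demographic_model"`: `intercept`, named
#'   `coefficients`, `reference` values (means of transformed covariates),
#'   `residual_sd`, `r_squared`, and the transform names.
#' @examples
#' age <- runif(200, 20, 90)
#' raw <- 30 - 0.2 * (age - 50) + rnorm(200, sd = 2)
#' fit_adjustment(raw, data.frame(age = age))
#' @export
fit_adjustment <- function(raw_scores, covariates, transforms = NULL) {
  if (!is.numeric(raw_scores) || any(!is.finite(raw_scores))) {
    stop("'raw_scores' must be numeric with no missing values", call. = FALSE)
  }
  if (!is.data.frame(covariates) || ncol(covariates) == 0L) {
    stop("'covariates' must be a data frame with at least one column",
         call. = FALSE)
  }
  if (nrow(covariates) != length(raw_scores)) {
    stop("'covariates' must have one row per raw score", call. = FALSE)
  }
  if (anyNA(covariates)) {
    stop("'covariates' must have no missing values", call. = FALSE)
  }
  tf <- resolve_transforms(names(covariates), transforms)
  enc <- encode_categorical(covariates)
  X <- transformed_design(enc$data, tf)
  if (length(raw_scores) <= ncol(X) + 1L) {
    stop("too few observations to fit the adjustment model", call. = FALSE)
  }
  fit <- stats::lm(raw_scores ~ ., data = X)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    bad <- names(beta)[is.na(beta)]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(
    intercept = unname(beta[1L]),
    coefficients = beta[-1L],
    reference = vapply(X, mean, numeric(1)),
    residual_sd = summary(fit)$sigma,
    r_squared = summary(fit)$r.squared,
    transforms = vapply(tf, attr, character(1), "transform_name"),
    levels = enc$levels,
    transform_funs = tf
  ), class = "demographic_model")
}

resolve_transforms <- function(cols, transforms) {
  builtin <- list(identity = identity, log = log, sqrt = sqrt)
  out <- lapply(cols, function(nm) {
    t <- if (!is.null(transforms) && nm %in% names(transforms)) transforms[[nm]] else "identity"
    if (is.character(t)) {
      if (!t %in% names(builtin)) {
        stop(sprintf("unknown transform '%s' for covariate '%s'", t, nm),
             call. = FALSE)
      }
      f <- builtin[[t]]
      attr(f, "transform_name") <- t
    } else if (is.function(t)) {
      f <- t
      attr(f, "transform_name") <- "custom"
    } else {
      stop(sprintf("transform for '%s' must be a name or a function", nm),
           call. = FALSE)
    }
    f
  })
  names(out) <- cols
  out
}

# Contrast-code two-level categorical columns 0/1 (first level in sort
# order = 0). At fit time levels are inferred from the data; at adjustment
# time the fitted levels are reused so single-row prediction works.
encode_categorical <- function(covariates, levels = NULL) {
  lev_out <- list()
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    if (is.character(x) || is.factor(x)) {
      lev <- if (!is.null(levels) && nm %in% names(levels)) {
        levels[[nm]]
      } else {
        sort(unique(as.character(x)))
      }
      if (length(lev) != 2L) {
        stop(sprintf("categorical covariate '%s' must have exactly 2 levels",
                     nm), call. = FALSE)
      }
      if (!all(as.character(x) %in% lev)) {
        stop(sprintf("covariate '%s' has values outside the fitted levels (%s)",
                     nm, paste(lev, collapse = ", ")), call. = FALSE)
      }
      covariates[[nm]] <- as.numeric(as.character(x) == lev[2L])
      lev_out[[nm]] <- lev
    }
  }
  list(data = covariates, levels = lev_out)
}

# Apply per-column transforms to the (already numeric) design columns.
transformed_design <- function(covariates, tf) {
  X <- lapply(names(covariates), function(nm) {
    v <- tf[[nm]](covariates[[nm]])
    if (any(!is.finite(v))) {
      stop(sprintf("transform of covariate '%s' produced non-finite values",
                   nm), call. = FALSE)
    }
    v
  })
  names(X) <- names(covariates)
  as.data.frame(X)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic adjustment model (OLS)\n")
  cat(sprintf("  intercept: %.4g; residual sd: %.4g; R-squared: %.3f\n",
              x$intercept, x$residual_sd, x$r_squared))
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %s (%s): beta = %.4g, reference = %.4g\n",
                nm, x$transforms[[nm]], x$coefficients[[nm]], x$reference[[nm]]))
  }
  invisible(x)
}

#' Adjust raw scores for demographic effects
#'
#' Removes the fitted demographic contribution from each raw score:
#' `adjusted = raw - sum_j beta_j * (t_j(x_j) - reference_j)`. At the
#' reference covariate values the adjustment is zero, and over the fitting
#' sample the mean adjustment is zero up to numerical tolerance.
#'
#' @param raw_scores Numeric vector of raw scores.
#' @param covariates Data frame with the columns the model was fitted on.
#' @param model A [fit_adjustment()] result.
#' @return Numeric vector of adjusted scores.
#' @export
adjust_scores <- function(raw_scores, covariates, model) {
  stopifnot(inherits(model, "demographic_model"))
  if (!is.numeric(raw_scores) || any(!is.finite(raw_scores))) {
    stop("'raw_scores' must be numeric with no missing values", call. = FALSE)
  }
  need <- names(model$coefficients)
  if (!is.data.frame(covariates) || !all(need %in% names(covariates))) {
    miss <- setdiff(need, names(covariates))
    stop(sprintf("covariate schema mismatch: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(covariates) != length(raw_scores)) {
    stop("'covariates' must have one row per raw score", call. = FALSE)
  }
  tf <- if (!is.null(model$transform_funs)) {
    model$transform_funs[need]
  } else {
    resolve_transforms(need, as.list(model$transforms))
  }
  enc <- encode_categorical(covariates[need], model$levels)
  X <- transformed_design(enc$data, tf)
  contrib <- as.matrix(X) %*% model$coefficients -
    sum(model$coefficients * model$reference[need])
  raw_scores - as.numeric(contrib)
}
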