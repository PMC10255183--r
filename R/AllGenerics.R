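# Accessor generics; slot access stays internal to the package.

#' Accessors for LipoProfile result objects
#'
#' @param x a \linkS4class{LipoproteinCohort}, \linkS4class{AnalysisDataset},
#'   \linkS4class{CoefficientTrace} or \linkS4class{ProfileModel}.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @return `concentrationMatrix()`: subjects × 12 matrix of lipoprotein
#'   concentrations (missing values possible).
#' @export
setGeneric("concentrationMatrix", function(x, ...) standardGeneric("concentrationMatrix"))

#' @rdname accessors
#' @export
setMethod("concentrationMatrix", "LipoproteinCohort", function(x, ...)
  t(assay(x, "concentrations")))

#' @rdname accessors
#' @return `intMatrix()`: subjects × 12 matrix of inverse-normal-transformed
#'   predictors (the design matrix for the Lasso).
#' @export
setGeneric("intMatrix", function(x, ...) standardGeneric("intMatrix"))

#' @rdname accessors
#' @export
setMethod("intMatrix", "AnalysisDataset", function(x, ...) t(assay(x, "int")))

#' @rdname accessors
#' @param outcome one of `"tl"`, `"tert"`, `"wrap53"`.
#' @return `outcomeVector()`: length-n fully imputed outcome on the analysis
#'   scale (tl raw T/S; tert/wrap53 log10).
#' @export
setGeneric("outcomeVector", function(x, outcome, ...) standardGeneric("outcomeVector"))

#' @rdname accessors
#' @export
setMethod("outcomeVector", "AnalysisDataset", function(x, outcome, ...) {
  outcome <- match.arg(outcome, outcomeNames())
  colData(x)[[paste0("y_", outcome)]]
})

#' @rdname accessors
#' @return `excludedFlags()`: logical vector marking observations excluded as
#'   outliers (and re-imputed) for the given outcome.
#' @export
setGeneric("excludedFlags", function(x, outcome, ...) standardGeneric("excludedFlags"))

#' @rdname accessors
#' @export
setMethod("excludedFlags", "AnalysisDataset", function(x, outcome, ...) {
  outcome <- match.arg(outcome, outcomeNames())
  colData(x)[[paste0("excluded_", outcome)]]
})

#' @rdname accessors
#' @return `covariateMatrix()`: subjects × 6 numeric matrix of covariates
#'   (age, sex, bmi, dyslipidemia, statins, leisure_pa).
#' @export
setGeneric("covariateMatrix", function(x, ...) standardGeneric("covariateMatrix"))

covariateMatrixFromColData <- function(x) {
  cd <- colData(x)
  m <- vapply(covariateNames(), function(v) as.numeric(cd[[v]]),
              numeric(nrow(cd)))
  rownames(m) <- colnames(x)
  m
}

#' @rdname accessors
#' @export
setMethod("covariateMatrix", "LipoproteinCohort", covariateMatrixFromColData)

#' @rdname accessors
#' @export
setMethod("covariateMatrix", "AnalysisDataset", covariateMatrixFromColData)

#' @rdname accessors
#' @return `coefMatrix()`: iterations × predictors Lasso coefficient matrix.
#' @export
setGeneric("coefMatrix", function(x, ...) standardGeneric("coefMatrix"))

#' @rdname accessors
#' @export
setMethod("coefMatrix", "CoefficientTrace", function(x, ...) x@coefs)

#' @rdname accessors
#' @return `heldoutPredictions()`: per-subject held-out predictions.
#' @export
setGeneric("heldoutPredictions", function(x, ...) standardGeneric("heldoutPredictions"))

#' @rdname accessors
#' @export
setMethod("heldoutPredictions", "CoefficientTrace", function(x, ...) {
  p <- x@heldout
  names(p) <- x@subjects
  p
})

#' @rdname accessors
#' @return `tunedLambdas()`: per-iteration tuned penalty values.
#' @export
setGeneric("tunedLambdas", function(x, ...) standardGeneric("tunedLambdas"))

#' @rdname accessors
#' @export
setMethod("tunedLambdas", "CoefficientTrace", function(x, ...) x@lambdas)

#' @rdname accessors
#' @return `selectedVariables()`: names of the stability-selected variables.
#' @export
setGeneric("selectedVariables", function(x, ...) standardGeneric("selectedVariables"))

#' @rdname accessors
#' @export
setMethod("selectedVariables", "ProfileModel", function(x, ...) x@selected)

#' @rdname accessors
#' @return `profileWeights()`: averaged coefficients of the selected
#'   variables (named numeric).
#' @export
setGeneric("profileWeights", function(x, ...) standardGeneric("profileWeights"))

#' @rdname accessors
#' @export
setMethod("profileWeights", "ProfileModel", function(x, ...) x@weights)

#' @rdname accessors
#' @return `retentionCounts()`: per-variable count of LOOCV iterations with a
#'   nonzero coefficient.
#' @export
setGeneric("retentionCounts", function(x, ...) standardGeneric("retentionCounts"))

#' @rdname accessors
#' @export
setMethod("retentionCounts", "ProfileModel", function(x, ...) x@retentionCounts)

#' @rdname accessors
#' @return `weightIntervals()`: data.frame with the selected variables'
#'   averaged weights and 95% percentile intervals.
#' @export
setGeneric("weightIntervals", function(x, ...) standardGeneric("weightIntervals"))

#' @rdname accessors
#' @export
setMethod("weightIntervals", "ProfileModel", function(x, ...)
  data.frame(variable = x@selected, weight = unname(x@weights),
             ci_lower = unname(x@ciLower), ci_upper = unname(x@ciUpper),
             retained = unname(x@retentionCounts[x@selected]),
             row.names = NULL))
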