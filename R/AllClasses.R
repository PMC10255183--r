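#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData "assay<-" "assays<-" "colData<-"
#' @importFrom S4Vectors DataFrame metadata "metadata<-" SimpleList
NULL

#' Subject-level lipoprotein cohort
#'
#' A \linkS4class{SummarizedExperiment} holding one assay,
#' `"concentrations"`: the 12 lipoprotein particle concentrations (rows, in
#' the order of [lipoproteinVocabulary()]) by subjects (columns). `colData`
#' carries the six covariates (age, sex, bmi, dyslipidemia, statins,
#' leisure_pa) and the three outcomes (tl = telomere T/S ratio, tert and
#' wrap53 = relative expression). Missing values are allowed in the assay and
#' the outcomes, observed values must be strictly positive, and no variable
#' may exceed 20% missingness (the screening rule applied before any
#' imputation is attempted).
#'
#' @seealso [simulateCohort()], [readCohortCSV()], [preprocessCohort()]
#' @export
setClass("LipoproteinCohort", contains = "SummarizedExperiment")

setValidity("LipoproteinCohort", function(object) {
  msg <- character(0)
  if (!"concentrations" %in% names(assays(object)))
    msg <- c(msg, "assay 'concentrations' is required")
  else {
    m <- assay(object, "concentrations")
    if (!identical(rownames(m), lipoproteinVocabulary()))
      msg <- c(msg, "assay rows must be the 12 lipoprotein vocabulary names, in order")
    if (any(m <= 0, na.rm = TRUE))
      msg <- c(msg, "observed lipoprotein concentrations must be strictly positive")
    if (ncol(m) > 0 && any(rowMeans(is.na(m)) > 0.20))
      msg <- c(msg, "a lipoprotein variable exceeds 20% missingness")
  }
  cd <- colData(object)
  need <- c(covariateNames(), outcomeNames())
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  for (o in intersect(outcomeNames(), colnames(cd))) {
    v <- cd[[o]]
    if (any(v <= 0, na.rm = TRUE))
      msg <- c(msg, paste0("observed ", o, " values must be strictly positive"))
    if (length(v) > 0 && mean(is.na(v)) > 0.20)
      msg <- c(msg, paste0(o, " exceeds 20% missingness"))
  }
  if (length(msg)) msg else TRUE
})

#' Preprocessed analysis dataset
#'
#' Result of [preprocessCohort()]: a \linkS4class{SummarizedExperiment} with
#' assays `"imputed"` (completed concentrations, original scale) and `"int"`
#' (inverse-normal-transformed predictors, each variable rank-normal with
#' mean 0). `colData` holds the covariates, the fully imputed outcome vectors
#' `y_tl` (T/S ratio scale), `y_tert` and `y_wrap53` (log10 scale), and the
#' per-outcome logical exclusion flags `excluded_tl` / `excluded_tert` /
#' `excluded_wrap53` marking observations removed as outliers and re-imputed.
#' `metadata()` carries per-cell provenance (`"observed"`, `"imputed"`,
#' `"excluded-then-imputed"`) and the processing log.
#'
#' @export
setClass("AnalysisDataset", contains = "SummarizedExperiment")

setValidity("AnalysisDataset", function(object) {
  msg <- character(0)
  for (a in c("imputed", "int"))
    if (!a %in% names(assays(object)))
      msg <- c(msg, paste0("assay '", a, "' is required"))
    else if (anyNA(assay(object, a)))
      msg <- c(msg, paste0("assay '", a, "' must be complete"))
  cd <- colData(object)
  for (o in outcomeNames()) {
    y <- cd[[paste0("y_", o)]]
    if (is.null(y) || anyNA(y))
      msg <- c(msg, paste0("y_", o, " must be present and complete"))
    if (is.null(cd[[paste0("excluded_", o)]]))
      msg <- c(msg, paste0("excluded_", o, " flags missing"))
  }
  if (length(msg)) msg else TRUE
})

#' Per-iteration Lasso coefficients from leave-one-out cross-validation
#'
#' One row per LOOCV iteration: the fitted coefficient vector (on the
#' rank-normal predictor scale), intercept, tuned penalty, and the held-out
#' prediction for the left-out subject (computed without ever seeing that
#' subject's outcome).
#'
#' @slot coefs numeric matrix, iterations × predictors.
#' @slot intercepts numeric, per-iteration intercepts.
#' @slot lambdas numeric, per-iteration tuned penalties.
#' @slot heldout numeric, `heldout[i]` predicts subject i from the model
#'   trained without subject i.
#' @slot subjects character, subject identifiers in row order.
#' @slot outcome character scalar, name of the modeled outcome.
#' @export
setClass("CoefficientTrace",
  representation(coefs = "matrix", intercepts = "numeric", lambdas = "numeric",
                 heldout = "numeric", subjects = "character",
                 outcome = "character"))

setValidity("CoefficientTrace", function(object) {
  n <- nrow(object@coefs)
  msg <- character(0)
  if (length(object@intercepts) != n) msg <- c(msg, "intercepts length != iterations")
  if (length(object@lambdas) != n) msg <- c(msg, "lambdas length != iterations")
  if (length(object@heldout) != n) msg <- c(msg, "heldout length != iterations")
  if (length(object@subjects) != n) msg <- c(msg, "subjects length != iterations")
  if (is.null(colnames(object@coefs))) msg <- c(msg, "coefs must have column names")
  if (length(msg)) msg else TRUE
})

#' Stability-selected lipoprotein profile
#'
#' Variables retained by the consistency rule (nonzero in at least
#' ceiling(stabilityFraction × N) of the N LOOCV iterations), their averaged
#' coefficients (zeros included unless averaged nonzero-only), and 95%
#' percentile intervals across iterations. The intervals are descriptive —
#' LOOCV iterations share almost all their data — not inferential.
#'
#' @slot variables character, all candidate predictor names.
#' @slot selected character, the retained subset.
#' @slot weights named numeric over `selected` (averaged coefficients).
#' @slot ciLower,ciUpper named numeric over `selected`, 2.5th/97.5th
#'   percentiles of the per-iteration coefficients.
#' @slot retentionCounts named integer over `variables`, number of iterations
#'   with a nonzero coefficient.
#' @slot threshold integer, minimum count required for retention.
#' @slot nIterations integer, number of LOOCV iterations N.
#' @export
setClass("ProfileModel",
  representation(variables = "character", selected = "character",
                 weights = "numeric", ciLower = "numeric", ciUpper = "numeric",
                 retentionCounts = "integer", threshold = "integer",
                 nIterations = "integer"))

setValidity("ProfileModel", function(object) {
  msg <- character(0)
  if (!all(object@selected %in% object@variables))
    msg <- c(msg, "selected must be a subset of variables")
  if (!identical(names(object@weights), object@selected))
    msg <- c(msg, "weights must be named by the selected variables")
  if (!identical(names(object@retentionCounts), object@variables))
    msg <- c(msg, "retentionCounts must cover all variables")
  bad <- object@variables[object@retentionCounts >= object@threshold]
  if (!setequal(bad, object@selected))
    msg <- c(msg, "selected set inconsistent with retention counts and threshold")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LipoproteinCohort", function(object) {
  cat("LipoproteinCohort:", ncol(object), "subjects x", nrow(object),
      "lipoprotein variables\n")
  m <- assay(object, "concentrations")
  cat("  missing lipoprotein cells:", sum(is.na(m)),
      sprintf("(%.2f%%)\n", 100 * mean(is.na(m))))
  ymiss <- vapply(outcomeNames(), function(o) sum(is.na(colData(object)[[o]])), 0L)
  cat("  missing outcomes:", paste(paste0(names(ymiss), "=", ymiss), collapse = " "), "\n")
})

setMethod("show", "AnalysisDataset", function(object) {
  cat("AnalysisDataset:", ncol(object), "subjects,",
      nrow(object), "rank-normal predictors, outcomes y_tl / y_tert / y_wrap53\n")
  ex <- vapply(outcomeNames(), function(o)
    sum(colData(object)[[paste0("excluded_", o)]]), 0L)
  cat("  outlier-excluded (re-imputed):",
      paste(paste0(names(ex), "=", ex), collapse = " "), "\n")
})

setMethod("show", "CoefficientTrace", function(object) {
  cat("CoefficientTrace (", object@outcome, "): ", nrow(object@coefs),
      " LOOCV iterations x ", ncol(object@coefs), " predictors\n", sep = "")
  cnt <- colSums(object@coefs != 0)
  top <- sort(cnt, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top))
    cat("  nonzero counts (top):",
        paste(paste0(names(head(top, 5)), "=", head(top, 5)), collapse = " "), "\n")
})

setMethod("show", "ProfileModel", function(object) {
  if (length(object@selected) == 0) {
    cat("ProfileModel: no stable profile (no variable reached",
        object@threshold, "of", object@nIterations, "iterations)\n")
    return(invisible(NULL))
  }
  cat("ProfileModel:", length(object@selected), "variables retained (>=",
      object@threshold, "of", object@nIterations, "iterations)\n")
  df <- data.frame(weight = round(object@weights, 4),
                   ci95 = sprintf("[%.4f, %.4f]", object@ciLower, object@ciUpper),
                   retained = object@retentionCounts[object@selected])
  print(df)
})
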