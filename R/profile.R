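#' Stability selection over a LOOCV coefficient trace
#'
#' Retains variable v iff its coefficient is nonzero in at least
#' `ceiling(stabilityFraction * N)` of the N leave-one-out iterations. At
#' N = 54 with the default fraction 48/54 the threshold is exactly 48
#' iterations (88.89%). Averaged weights and 95% percentile intervals for
#' the retained variables come from [averageWeights()].
#'
#' @param trace a \linkS4class{CoefficientTrace}.
#' @param stabilityFraction retention fraction in (0, 1\]; default 48/54.
#' @param average `"all"` (default, zeros included) or `"nonzero_only"`.
#' @return a \linkS4class{ProfileModel}; an empty selection is returned as a
#'   model with no variables (flagged by `show()` as "no stable profile").
#' @export
stabilitySelect <- function(trace, stabilityFraction = 48 / 54,
                            average = c("all", "nonzero_only")) {
  stopifnot(is(trace, "CoefficientTrace"),
            stabilityFraction > 0, stabilityFraction <= 1)
  average <- match.arg(average)
  cm <- coefMatrix(trace)
  N <- nrow(cm)
  counts <- colSums(cm != 0)
  threshold <- as.integer(ceiling(stabilityFraction * N))
  selected <- colnames(cm)[counts >= threshold]
  aw <- averageWeights(trace, selected, average = average)
  methods::new("ProfileModel", variables = colnames(cm), selected = selected,
               weights = stats::setNames(aw$weight, selected),
               ciLower = stats::setNames(aw$ci_lower, selected),
               ciUpper = stats::setNames(aw$ci_upper, selected),
               retentionCounts = stats::setNames(as.integer(counts), colnames(cm)),
               threshold = threshold, nIterations = as.integer(N))
}

#' Average LOOCV coefficients and 95% percentile intervals
#'
#' The weight of each variable is the mean of its coefficient over all N
#' iterations (zeros included, unless `average = "nonzero_only"`); the
#' interval is the 2.5th/97.5th percentile of the N per-iteration
#' coefficients. The iterations share n − 2 of their n − 1 training rows,
#' so the interval is descriptive, not inferential.
#'
#' @param trace a \linkS4class{CoefficientTrace}.
#' @param selected character vector of variables to summarize (may be
#'   empty, giving a zero-row result).
#' @param average `"all"` or `"nonzero_only"`.
#' @return data.frame with columns variable, weight, ci_lower, ci_upper.
#' @export
averageWeights <- function(trace, selected, average = c("all", "nonzero_only")) {
  stopifnot(is(trace, "CoefficientTrace"))
  average <- match.arg(average)
  cm <- coefMatrix(trace)
  stopifnot(all(selected %in% colnames(cm)))
  rows <- lapply(selected, function(v) {
    b <- cm[, v]
    w <- if (average == "nonzero_only") mean(b[b != 0]) else mean(b)
    q <- stats::quantile(b, c(0.025, 0.975), type = 7, names = FALSE)
    data.frame(variable = v, weight = w, ci_lower = q[1], ci_upper = q[2])
  })
  if (length(rows) == 0)
    return(data.frame(variable = character(0), weight = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0)))
  do.call(rbind, rows)
}

#' Lipoprotein profile score
#'
#' The per-subject score is the weighted sum of the selected rank-normal
#' lipoprotein variables, using the averaged LOOCV coefficients as weights.
#' No intercept is added: the score is used for correlation, which is
#' location-invariant.
#'
#' @param X design matrix whose columns cover the model's selected
#'   variables.
#' @param model a \linkS4class{ProfileModel}.
#' @return length-n numeric score vector (all zeros for an empty model).
#' @export
profileScore <- function(X, model) {
  stopifnot(is(model, "ProfileModel"))
  X <- as.matrix(X)
  sel <- selectedVariables(model)
  if (length(sel) == 0) return(rep(0, nrow(X)))
  missing <- setdiff(sel, colnames(X))
  if (length(missing))
    stop("X lacks selected columns: ", paste(missing, collapse = ", "))
  as.vector(X[, sel, drop = FALSE] %*% profileWeights(model))
}
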