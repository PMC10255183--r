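#' Pearson correlation with degenerate-input checks
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return product-moment correlation.
#' @export
pearsonR <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  stats::cor(x, y)
}

#' Fisher-z confidence interval for a correlation
#'
#' Bounds are \eqn{\tanh(\mathrm{atanh}(r) \mp z_{(1+level)/2} /
#' \sqrt{n - 3})}: symmetric around atanh(r) in z-space.
#'
#' @param r correlation, |r| < 1.
#' @param n sample size, > 3.
#' @param level confidence level (default 0.95).
#' @return numeric c(lower, upper).
#' @examples
#' round(fisherCI(0.379, 54), 3)  # c(0.124, 0.587)
#' @export
fisherCI <- function(r, n, level = 0.95) {
  if (abs(r) >= 1) stop("|r| must be below 1")
  if (n <= 3) stop("need n > 3")
  z <- atanh(r)
  half <- stats::qnorm((1 + level) / 2) / sqrt(n - 3)
  c(lower = tanh(z - half), upper = tanh(z + half))
}

#' Two-sided p-value for a correlation
#'
#' Exact t reference: \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} on n − 2
#' degrees of freedom.
#'
#' @param r correlation, |r| < 1.
#' @param n sample size, > 2.
#' @return two-sided p-value in (0, 1].
#' @examples
#' round(pearsonPValue(0.347, 54), 3)  # 0.010
#' @export
pearsonPValue <- function(r, n) {
  if (abs(r) >= 1) stop("|r| must be below 1")
  if (n <= 2) stop("need n > 2")
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Root-mean-square error
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return sqrt(mean squared difference), in outcome units.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  stopifnot(length(observed) >= 1)
  sqrt(mean((observed - predicted)^2))
}

#' Evaluate a profile against an outcome
#'
#' The headline evaluation correlates the observed outcome with the
#' held-out LOOCV predictions; a score-based evaluation (outcome vs the
#' profile score) is reported alongside when a score is supplied.
#'
#' @param y observed outcome (analysis scale), complete.
#' @param heldout held-out predictions from [runLOOCV()].
#' @param score optional profile score from [profileScore()].
#' @param level confidence level (default 0.95).
#' @return data.frame with one row per basis (`"heldout"`, `"score"`) and
#'   columns r, ci_lower, ci_upper, p_value, rmse, n.
#' @export
evaluateProfile <- function(y, heldout, score = NULL, level = 0.95) {
  stopifnot(length(y) == length(heldout), !anyNA(y), !anyNA(heldout))
  one <- function(pred, basis) {
    r <- pearsonR(y, pred)
    # |r| = 1 (perfect prediction) degenerates the Fisher/t machinery; report
    # the point interval and the p-value at the representable boundary
    rc <- min(max(r, -(1 - 1e-15)), 1 - 1e-15)
    ci <- if (abs(r) >= 1) c(lower = r, upper = r) else fisherCI(r, length(y), level)
    data.frame(basis = basis, r = r, ci_lower = ci[["lower"]],
               ci_upper = ci[["upper"]], p_value = pearsonPValue(rc, length(y)),
               rmse = rmse(y, pred), n = length(y), row.names = NULL)
  }
  out <- one(heldout, "heldout")
  if (!is.null(score)) out <- rbind(out, one(score, "score"))
  out
}
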