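#' Rank-based inverse normal transformation
#'
#' Maps values to standard normal quantiles through their ranks using the
#' Blom offset: \eqn{\Phi^{-1}((r_i - 3/8)/(n + 1/4))}, where \eqn{r_i} is
#' the average rank (ties share a rank, hence map to equal outputs). The
#' result is rank-normal with mean exactly 0 and SD close to 1.
#'
#' @param x numeric vector, length >= 3, no missing values (impute first),
#'   not constant.
#' @return the transformed vector.
#' @examples
#' inverseNormalTransform(c(10, 20, 30))
#' @export
inverseNormalTransform <- function(x) {
  if (anyNA(x)) stop("missing values: impute before transforming")
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  if (length(unique(x)) == 1L)
    stop("constant input: ranks carry no information")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Iterative random-forest imputation
#'
#' Completes a numeric matrix by the iterative random-forest scheme: missing
#' cells start at their column means; columns are visited in increasing
#' order of missingness, each regressed on all the others with a random
#' forest fit on its observed rows and its missing cells replaced by forest
#' predictions; the sweep repeats until the sum of squared changes in the
#' imputed cells increases (the previous iteration is then returned) or
#' `maxIter` is reached. Observed cells are never modified.
#'
#' @param m numeric matrix, subjects × variables; >= 2 columns, >= 10 rows,
#'   every column < 20% missing and not entirely missing.
#' @param nTrees trees per forest (default 100).
#' @param maxIter maximum sweeps (default 10).
#' @param seed integer seed.
#' @return the completed matrix.
#' @export
rfImpute <- function(m, nTrees = 100, maxIter = 10, seed = 1) {
  stopifnot(is.matrix(m), is.numeric(m))
  n <- nrow(m); p <- ncol(m)
  if (p < 2) stop("need at least 2 columns")
  if (n < 10) stop("need at least 10 rows")
  nmiss <- colSums(is.na(m))
  if (any(nmiss == n)) stop("a column is entirely missing")
  if (any(nmiss / n >= 0.20)) stop("a column has >= 20% missing values")
  if (all(nmiss == 0)) return(m)

  obs <- !is.na(m)
  cur <- m
  for (j in seq_len(p)) cur[!obs[, j], j] <- mean(m[, j], na.rm = TRUE)
  order_j <- order(nmiss)
  order_j <- order_j[nmiss[order_j] > 0]

  withSeed(seed, {
    prev <- cur
    lastDelta <- Inf
    for (iter in seq_len(maxIter)) {
      before <- cur
      for (j in order_j) {
        oj <- obs[, j]
        fit <- randomForest::randomForest(
          x = cur[oj, -j, drop = FALSE], y = m[oj, j], ntree = nTrees)
        cur[!oj, j] <- stats::predict(fit, cur[!oj, -j, drop = FALSE])
      }
      delta <- sum((cur[!obs] - before[!obs])^2)
      if (delta > lastDelta) {
        cur <- before  # criterion stopped improving; keep previous sweep
        break
      }
      lastDelta <- delta
    }
  })
  stopifnot(identical(cur[obs], m[obs]))
  cur
}

#' Robust outcome outlier screen
#'
#' Computes the robust z statistic \eqn{s_i = |x_i - median(x)| / MAD(x)} on
#' the observed values and flags the indices whose statistic strictly
#' exceeds the empirical `percentile`-th percentile of the statistics
#' (type-7 quantile). At n = 54 and the 99th percentile at most one value
#' can exceed the cut-off, matching the behavior of excluding a single
#' observation per outcome.
#'
#' @param x numeric vector, length >= 10; missing values are ignored when
#'   computing the statistic and never flagged.
#' @param percentile cut-off percentile (default 99).
#' @return integer vector of flagged indices (possibly empty).
#' @export
detectOutcomeOutliers <- function(x, percentile = 99) {
  obs <- which(!is.na(x))
  if (length(obs) < 10) stop("need at least 10 observed values")
  med <- stats::median(x[obs])
  madv <- stats::mad(x[obs])
  if (madv == 0) stop("MAD is zero: spread is degenerate")
  s <- abs(x - med) / madv
  cut <- stats::quantile(s[obs], percentile / 100, type = 7, names = FALSE)
  which(!is.na(s) & s > cut)
}

#' Base-10 logarithm with positivity check
#'
#' @param x numeric vector; observed values must be strictly positive
#'   (missing values propagate).
#' @return `log10(x)`.
#' @export
log10Transform <- function(x) {
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad))
    stop("non-positive value at row ", bad[1], ": log10 undefined")
  log10(x)
}

#' Chained-equation imputation with predictive mean matching
#'
#' Imputes the missing cells of `targets` by iterating chained equations:
#' each incomplete column is regressed (least squares) on the complete
#' predictors plus the other target columns at their current values, and
#' every missing cell is filled with the observed value of one of the 5
#' donors whose fitted means are closest to the missing cell's fitted mean
#' (predictive mean matching). One completed dataset is returned; imputed
#' values are always drawn from observed donors and hence lie within the
#' observed range. Observed cells are never modified.
#'
#' @param targets numeric matrix n × k with missing cells; each column must
#'   be < 20% missing and have observed donors.
#' @param predictors complete numeric matrix n × m.
#' @param nCycles sweeps over the target columns (default 10).
#' @param seed integer seed.
#' @param donors donor-pool size (default 5).
#' @return completed n × k matrix.
#' @export
miceImpute <- function(targets, predictors, nCycles = 10, seed = 1, donors = 5) {
  stopifnot(is.matrix(targets), is.matrix(predictors),
            nrow(targets) == nrow(predictors))
  if (anyNA(predictors)) stop("predictors must be complete")
  n <- nrow(targets)
  nmiss <- colSums(is.na(targets))
  if (any(nmiss == n)) stop("a target column has no observed donors")
  if (any(nmiss / n >= 0.20)) stop("a target column has >= 20% missing values")
  if (all(nmiss == 0)) return(targets)

  obs <- !is.na(targets)
  cur <- targets
  withSeed(seed, {
    # initialize missing cells with random observed donors of their column
    for (j in which(nmiss > 0)) {
      oj <- which(obs[, j])
      cur[!obs[, j], j] <- cur[sample(oj, nmiss[j], replace = TRUE), j]
    }
    for (cycle in seq_len(nCycles)) {
      for (j in which(nmiss > 0)) {
        oj <- obs[, j]
        D <- cbind(1, predictors, cur[, -j, drop = FALSE])
        fit <- stats::lm.fit(D[oj, , drop = FALSE], targets[oj, j])
        beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        yhat <- as.vector(D %*% beta)
        for (i in which(!oj)) {
          d <- abs(yhat[oj] - yhat[i])
          pool <- which(oj)[order(d)][seq_len(min(donors, sum(oj)))]
          cur[i, j] <- targets[sample(pool, 1L), j]
        }
      }
    }
  })
  stopifnot(identical(cur[obs], targets[obs]))
  cur
}

#' Full preprocessing pipeline
#'
#' Executes, in order: (1) iterative random-forest imputation of the 12
#' lipoprotein variables; (2) inverse normal transformation of each
#' lipoprotein variable (class totals transformed independently of their
#' subclasses); (3) robust 99th-percentile outlier screening of each
#' outcome (on the raw scale by default), flagged values set missing; (4)
#' log10 transformation of tert and wrap53; (5) chained-equation imputation
#' of the outcomes with covariates plus the transformed lipoproteins as
#' predictors. Rows are never dropped: exclusion means re-imputation, so the
#' output always has the cohort's full n.
#'
#' @param cohort a \linkS4class{LipoproteinCohort}; covariates must be
#'   complete.
#' @param percentile outlier cut-off percentile (default 99).
#' @param nTrees,maxIter forwarded to [rfImpute()].
#' @param nCycles forwarded to [miceImpute()].
#' @param outliersOnLog screen tert/wrap53 on the log10 scale instead of the
#'   raw scale (default FALSE; the raw-scale order matches the reported
#'   processing order).
#' @param seed integer master seed.
#' @return an \linkS4class{AnalysisDataset}.
#' @examples
#' ds <- preprocessCohort(simulateCohort(cohortConfig(), seed = 1), seed = 1)
#' ds
#' @export
preprocessCohort <- function(cohort, percentile = 99, nTrees = 100,
                             maxIter = 10, nCycles = 10,
                             outliersOnLog = FALSE, seed = 1) {
  stopifnot(is(cohort, "LipoproteinCohort"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  conc <- concentrationMatrix(cohort)           # n x 12
  lipoProv <- ifelse(is.na(conc), "imputed", "observed")
  withStage <- function(stage, expr)
    tryCatch(expr, error = function(e)
      stop("stage [", stage, "]: ", conditionMessage(e), call. = FALSE))

  imputed <- withStage("rf_impute",
    rfImpute(conc, nTrees = nTrees, maxIter = maxIter,
             seed = deriveSeed(seed, 101)))
  note("rf_impute: completed ", sum(is.na(conc)), " lipoprotein cells")

  X <- withStage("inverse_normal_transform",
                 apply(imputed, 2, inverseNormalTransform))
  rownames(X) <- rownames(imputed)
  note("inverse_normal_transform: 12 variables rank-normalized")

  cd <- colData(cohort)
  n <- ncol(cohort)
  yprov <- matrix("observed", n, 3, dimnames = list(colnames(cohort), outcomeNames()))
  yraw <- list()
  excl <- list()
  for (o in outcomeNames()) {
    v <- as.numeric(cd[[o]])
    yprov[is.na(v), o] <- "imputed"
    screenOn <- if (o != "tl" && outliersOnLog) log10Transform(v) else v
    flags <- withStage("detect_outcome_outliers",
                       detectOutcomeOutliers(screenOn, percentile))
    v[flags] <- NA_real_
    yprov[flags, o] <- "excluded-then-imputed"
    ex <- logical(n); ex[flags] <- TRUE
    excl[[o]] <- ex
    yraw[[o]] <- v
    note("detect_outcome_outliers(", o, "): excluded ", length(flags),
         " observation(s)")
  }
  yraw$tert <- withStage("log10_transform", log10Transform(yraw$tert))
  yraw$wrap53 <- withStage("log10_transform", log10Transform(yraw$wrap53))
  note("log10_transform: tert, wrap53")

  Y <- cbind(tl = yraw$tl, tert = yraw$tert, wrap53 = yraw$wrap53)
  covm <- covariateMatrix(cohort)
  if (anyNA(covm)) stop("stage [mice_impute]: covariates must be complete")
  Yc <- withStage("mice_impute",
    miceImpute(Y, cbind(covm, X), nCycles = nCycles,
               seed = deriveSeed(seed, 103)))
  note("mice_impute: completed ", sum(is.na(Y)), " outcome cells")

  cdOut <- DataFrame(as.data.frame(cd)[, covariateNames(), drop = FALSE],
                     y_tl = Yc[, "tl"], y_tert = Yc[, "tert"],
                     y_wrap53 = Yc[, "wrap53"],
                     excluded_tl = excl$tl, excluded_tert = excl$tert,
                     excluded_wrap53 = excl$wrap53,
                     row.names = colnames(cohort))
  methods::new("AnalysisDataset", SummarizedExperiment(
    assays = list(imputed = t(imputed), int = t(X)),
    colData = cdOut,
    metadata = list(provenance = list(lipoproteins = t(lipoProv),
                                      outcomes = yprov),
                    log = log, seed = seed,
                    percentile = percentile, outliersOnLog = outliersOnLog)))
}
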