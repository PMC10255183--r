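#' Lasso pipeline configuration
#'
#' @param nLambda penalty-grid size (default 100).
#' @param lambdaMinRatio smallest/largest grid penalty (default 1e-4).
#' @param nBoot bootstrap repetitions for penalty tuning within each
#'   training fold (default 25).
#' @param stabilityFraction retention fraction for stability selection;
#'   default 48/54, i.e. a variable must be nonzero in at least
#'   ceiling(stabilityFraction × N) of the N leave-one-out iterations.
#' @param seed master seed; per-fold and per-bootstrap streams are derived
#'   from it, so subject row order does not matter when fold seeds are
#'   matched to subjects.
#' @param penalizeCovariates if FALSE (default), covariates in the adjusted
#'   model carry penalty factor 0 and can never be shrunk away.
#' @param aggregate `"tune"` (default): the 25 bootstrap resamples tune the
#'   penalty by out-of-bag RMSE and a single model is fit at the tuned value;
#'   `"bagged"`: additionally the fold's coefficients are the average of 25
#'   bootstrap refits at the tuned penalty.
#' @param average `"all"` (default): profile weights average the coefficient
#'   over all N iterations, zeros included; `"nonzero_only"`: average over
#'   the iterations where the coefficient was retained.
#' @return a validated `lasso_config` list.
#' @export
lassoConfig <- function(nLambda = 100, lambdaMinRatio = 1e-4, nBoot = 25,
                        stabilityFraction = 48 / 54, seed = 1,
                        penalizeCovariates = FALSE,
                        aggregate = c("tune", "bagged"),
                        average = c("all", "nonzero_only")) {
  stopifnot(nLambda >= 2, lambdaMinRatio > 0, lambdaMinRatio < 1,
            nBoot >= 1, stabilityFraction > 0, stabilityFraction <= 1)
  structure(list(nLambda = nLambda, lambdaMinRatio = lambdaMinRatio,
                 nBoot = nBoot, stabilityFraction = stabilityFraction,
                 seed = seed, penalizeCovariates = penalizeCovariates,
                 aggregate = match.arg(aggregate),
                 average = match.arg(average)),
            class = "lasso_config")
}

# Smallest penalty at which all penalized coefficients are zero. With
# unpenalized columns present, y is first residualized on them (plus the
# intercept) so the entry point of the penalized path is exact.
lambdaMax <- function(X, y, penaltyFactor = rep(1, ncol(X))) {
  n <- nrow(X)
  free <- penaltyFactor == 0
  resid <- if (any(free)) {
    stats::lm.fit(cbind(1, X[, free, drop = FALSE]), y)$residuals
  } else {
    y - mean(y)
  }
  max(abs(crossprod(X[, !free, drop = FALSE], resid))) / n
}

#' Penalty grid for the Lasso path
#'
#' Log-spaced decreasing grid from \eqn{\lambda_{max} = \max_j
#' |X_j^T (y - \bar y)| / n} (the smallest penalty with an all-zero
#' solution) down to `lambdaMinRatio` times that value.
#'
#' @param X design matrix (the rank-normal predictors are already
#'   column-standardized); no zero-variance columns.
#' @param y response.
#' @param nLambda,lambdaMinRatio grid size and span.
#' @return decreasing numeric vector of length `nLambda`.
#' @export
lambdaPath <- function(X, y, nLambda = 100, lambdaMinRatio = 1e-4) {
  X <- as.matrix(X)
  if (nrow(X) < 5) stop("need at least 5 rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance column in the design")
  lmax <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
  if (lmax == 0) stop("response is orthogonal to every predictor (lambda_max = 0)")
  exp(seq(log(lmax), log(lmax * lambdaMinRatio), length.out = nLambda))
}

#' Fit a Gaussian Lasso at one penalty value
#'
#' Minimizes \eqn{(1/2n) \sum_i (y_i - \beta_0 - x_i \beta)^2 + \lambda
#' \sum_j w_j |\beta_j|} (coordinate descent via glmnet, warm-started along
#' a path ending exactly at `lambda`, convergence threshold 1e-12). At
#' `lambda >= lambda_max` the solution is exactly zero; at `lambda = 0` it
#' equals ordinary least squares for p < n.
#'
#' @param X design matrix (n × p).
#' @param y response.
#' @param lambda penalty value (>= 0).
#' @param penaltyFactor per-column penalty weights \eqn{w_j} (0 =
#'   unpenalized); default all 1.
#' @return list with `intercept` and named `coefficients`.
#' @export
fitLasso <- function(X, y, lambda, penaltyFactor = rep(1, ncol(X))) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, lambda >= 0, length(penaltyFactor) == p,
            all(is.finite(X)), all(is.finite(y)))
  cn <- colnames(X) %||% paste0("V", seq_len(p))

  zero <- function() list(intercept = mean(y),
                          coefficients = stats::setNames(rep(0, p), cn))
  lmax <- lambdaMax(X, y, penaltyFactor)
  if (all(penaltyFactor > 0) && lambda >= lmax && lmax > 0) return(zero())

  if (p == 1) {
    xc <- X[, 1] - mean(X[, 1]); yc <- y - mean(y)
    sxx <- sum(xc^2) / n
    if (sxx == 0) stop("zero-variance column")
    b <- softThreshold(sum(xc * yc) / n, lambda * penaltyFactor[1]) / sxx
    return(list(intercept = mean(y) - b * mean(X[, 1]),
                coefficients = stats::setNames(b, cn)))
  }

  top <- max(lmax, lambda, .Machine$double.eps)
  lseq <- exp(seq(log(top), log(max(lambda, top * 1e-4)), length.out = 30))
  lseq <- sort(unique(c(lseq, lambda)), decreasing = TRUE)
  # glmnet rescales penalty factors to sum to p; undo so lambda keeps the
  # stated objective's scale on the penalized columns
  adj <- if (all(penaltyFactor == 0)) 1 else sum(penaltyFactor) / p
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        lambda = lseq * adj, standardize = FALSE,
                        penalty.factor = penaltyFactor,
                        thresh = 1e-12, maxit = 1e7)
  k <- which.min(abs(fit$lambda - lambda * adj))
  beta <- as.numeric(fit$beta[, k])
  list(intercept = as.numeric(fit$a0[k]),
       coefficients = stats::setNames(beta, cn))
}

softThreshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Tune the Lasso penalty by bootstrap aggregation
#'
#' Draws `nBoot` bootstrap resamples of the rows; for each, fits the full
#' penalty path on the resample and scores every grid value by RMSE on the
#' out-of-bag rows. Returns the grid value minimizing the mean out-of-bag
#' RMSE, breaking ties toward the larger penalty (the sparser model). A
#' resample whose out-of-bag set is empty is redrawn.
#'
#' @param X,y training data.
#' @param grid decreasing penalty grid, from [lambdaPath()].
#' @param nBoot bootstrap repetitions (default 25).
#' @param seed integer seed.
#' @param penaltyFactor optional per-column penalty weights.
#' @return the tuned penalty (scalar); attribute `"oobRMSE"` carries the
#'   per-grid mean out-of-bag RMSE.
#' @export
tuneLambdaBootstrap <- function(X, y, grid, nBoot = 25, seed = 1,
                                penaltyFactor = rep(1, ncol(X))) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(nBoot >= 1, all(diff(grid) < 0))
  adj <- if (all(penaltyFactor == 0)) 1 else sum(penaltyFactor) / ncol(X)
  err <- withSeed(seed, {
    e <- matrix(NA_real_, nBoot, length(grid))
    for (b in seq_len(nBoot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), idx)
        if (length(oob) > 0) break
      }
      fit <- glmnet::glmnet(X[idx, , drop = FALSE], y[idx],
                            family = "gaussian", alpha = 1,
                            lambda = grid * adj, standardize = FALSE,
                            penalty.factor = penaltyFactor,
                            thresh = 1e-9, maxit = 1e7)
      pred <- stats::predict(fit, X[oob, , drop = FALSE])
      # glmnet may drop trailing path values; align by position
      kfit <- ncol(pred)
      e[b, seq_len(kfit)] <- sqrt(colMeans((pred - y[oob])^2))
    }
    e
  })
  mu <- colMeans(err)
  mu[is.na(mu)] <- Inf
  best <- which(mu <= min(mu) + 1e-12)[1]  # grid is decreasing: first = largest
  structure(grid[best], oobRMSE = mu)
}

#' Leave-one-out cross-validated Lasso
#'
#' For each subject i, tunes the penalty on the remaining n − 1 rows via
#' [tuneLambdaBootstrap()] (fold-specific stream derived from the master
#' seed), fits the Lasso there, records the coefficient vector, and predicts
#' subject i blindly. Subject i's outcome never enters its own prediction.
#'
#' @param X design matrix (n × p), n >= 10.
#' @param y response.
#' @param config a [lassoConfig()].
#' @param penaltyFactor optional per-column penalty weights.
#' @param foldSeeds optional integer vector of per-fold seeds (length n);
#'   defaults to streams derived from `config$seed` by fold index. Supplying
#'   subject-matched seeds makes the result invariant to row order.
#' @param outcome label stored on the trace.
#' @return a \linkS4class{CoefficientTrace}.
#' @export
runLOOCV <- function(X, y, config = lassoConfig(),
                     penaltyFactor = rep(1, ncol(X)),
                     foldSeeds = NULL, outcome = "y") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("need at least 10 subjects")
  stopifnot(length(y) == n, inherits(config, "lasso_config"))
  if (is.null(foldSeeds)) foldSeeds <- deriveSeed(config$seed, 1000 + seq_len(n))
  stopifnot(length(foldSeeds) == n)
  cn <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- cn
  subjects <- rownames(X) %||% as.character(seq_len(n))

  coefs <- matrix(NA_real_, n, ncol(X), dimnames = list(subjects, cn))
  intercepts <- lambdas <- heldout <- numeric(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      # canonical training-row order (by subject label) makes the bootstrap
      # draws, hence the whole fold, invariant to the input row order
      tr <- setdiff(seq_len(n), i)
      tr <- tr[order(subjects[tr])]
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      grid <- lambdaPath(Xtr, ytr, config$nLambda, config$lambdaMinRatio)
      lam <- tuneLambdaBootstrap(Xtr, ytr, grid, config$nBoot,
                                 seed = foldSeeds[i],
                                 penaltyFactor = penaltyFactor)
      fit <- fitLasso(Xtr, ytr, lam, penaltyFactor)
      if (config$aggregate == "bagged") {
        bag <- withSeed(deriveSeed(foldSeeds[i], 7), {
          acc <- c(fit$intercept, fit$coefficients) * 0
          for (b in seq_len(config$nBoot)) {
            idx <- sample.int(nrow(Xtr), nrow(Xtr), replace = TRUE)
            fb <- fitLasso(Xtr[idx, , drop = FALSE], ytr[idx], lam,
                           penaltyFactor)
            acc <- acc + c(fb$intercept, fb$coefficients)
          }
          acc / config$nBoot
        })
        fit <- list(intercept = bag[1], coefficients = bag[-1])
      }
      list(lam = lam, fit = fit)
    }, error = function(e)
      stop("LOOCV fold ", i, ": ", conditionMessage(e), call. = FALSE))
    coefs[i, ] <- res$fit$coefficients
    intercepts[i] <- res$fit$intercept
    lambdas[i] <- res$lam
    heldout[i] <- res$fit$intercept + sum(X[i, ] * res$fit$coefficients)
  }
  methods::new("CoefficientTrace", coefs = coefs, intercepts = intercepts,
               lambdas = lambdas, heldout = heldout, subjects = subjects,
               outcome = outcome)
}

#' Covariate-adjusted sensitivity analysis
#'
#' Reruns the LOOCV Lasso on the design `[X | covariates]`. With
#' `penalizeCovariates = FALSE` (default) the covariates carry penalty
#' factor 0, so adjustment can never be shrunk away. Stability selection and
#' the profile are computed over the lipoprotein columns only.
#'
#' @param X rank-normal lipoprotein matrix (n × p).
#' @param y response.
#' @param covariates complete numeric matrix (n × m); binary covariates
#'   coded 0/1. `m = 0` reduces to the unadjusted analysis.
#' @param config a [lassoConfig()].
#' @param foldSeeds,outcome forwarded to [runLOOCV()].
#' @return list with the full-design `trace`, the lipoprotein-only
#'   `lipoTrace`, and the stability-selected `model`.
#' @export
runAdjusted <- function(X, y, covariates, config = lassoConfig(),
                        foldSeeds = NULL, outcome = "y") {
  X <- as.matrix(X)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    trace <- runLOOCV(X, y, config, foldSeeds = foldSeeds, outcome = outcome)
    return(list(trace = trace, lipoTrace = trace,
                model = stabilitySelect(trace, config$stabilityFraction,
                                        average = config$average)))
  }
  covariates <- as.matrix(covariates)
  if (anyNA(covariates)) stop("covariates must be complete")
  qrd <- qr(cbind(1, covariates))
  if (qrd$rank < ncol(covariates) + 1)
    stop("collinear covariate with zero residual variance")
  cn <- colnames(covariates) %||% paste0("C", seq_len(ncol(covariates)))
  colnames(covariates) <- cn
  design <- cbind(X, covariates)
  pf <- c(rep(1, ncol(X)),
          rep(if (config$penalizeCovariates) 1 else 0, ncol(covariates)))
  trace <- runLOOCV(design, y, config, penaltyFactor = pf,
                    foldSeeds = foldSeeds, outcome = outcome)
  lipoTrace <- methods::new("CoefficientTrace",
                            coefs = trace@coefs[, colnames(X), drop = FALSE],
                            intercepts = trace@intercepts,
                            lambdas = trace@lambdas, heldout = trace@heldout,
                            subjects = trace@subjects, outcome = outcome)
  list(trace = trace, lipoTrace = lipoTrace,
       model = stabilitySelect(lipoTrace, config$stabilityFraction,
                               average = config$average))
}
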