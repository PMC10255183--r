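#' Synthetic cohort configuration
#'
#' Bundles the parameters of the synthetic prediabetic cohort generator. The
#' defaults reproduce the statistical structure the analysis assumes: n = 54
#' subjects; lognormal lipoprotein concentrations with within-class
#' correlation on the log scale; class totals equal to the sum of their three
#' subclasses times small lognormal measurement noise (making the
#' total/subclass collinearity explicit); a small-to-large HDL median
#' concentration ratio of 28; outcomes driven linearly by a sparse set of
#' lipoproteins on the rank-normal scale at weak signal strength; covariates
#' drawn from reference prediabetic-cohort summary moments; 2.16% average
#' missingness capped at 11.11% per variable; one gross outlier per outcome;
#' and five subjects with no outcome measurements at all.
#'
#' @param nSubjects number of subjects (>= 10; default 54).
#' @param classBlockRho within-class correlation of subclass
#'   log-concentrations, in (-1, 1).
#' @param logScaleMedians named positive vector of the 9 subclass median
#'   concentrations (class totals are derived as subclass sums). The default
#'   respects the size ordering (smaller particles more concentrated within
#'   VLDL/LDL) and a S-HDL-P / L-HDL-P median ratio of 28.
#' @param logSd lognormal shape (SD of log concentration) shared by the
#'   subclasses; default 0.25 (~25% coefficient of variation).
#' @param totalNoiseSd lognormal measurement-noise SD applied to the class
#'   totals on top of the subclass sum; default 0.03.
#' @param trueWeights named list with elements `tl`, `tert`, `wrap53`; each a
#'   named numeric vector of coefficients on the rank-normal lipoprotein
#'   scale (1 to 12 nonzero entries). Set an element to `NULL` (with
#'   `targetR` 0) for a pure-noise outcome.
#' @param targetR named numeric: intended population correlation between each
#'   outcome (on its analysis scale) and the true linear lipoprotein score,
#'   each in \[0, 1). Defaults to the observed profile correlations
#'   0.347 / 0.316 / 0.379.
#' @param outcomeLocation,outcomeScale location and scale of the outcomes on
#'   their analysis scale (tl: raw T/S ratio; tert, wrap53: log10). Defaults
#'   match the reference cohort's medians and interquartile ranges (TL 0.76 \[0.63, 0.88\],
#'   TERT 8.57 \[7.37, 11.05\], WRAP53 3.46 \[2.93, 3.72\]).
#' @param missingRateMean,missingRateMax mean and per-variable maximum
#'   missing fraction for the lipoprotein panel; both in \[0, 0.2), mean <=
#'   max. Defaults 0.0216 and 0.1111.
#' @param nOutliersPerOutcome gross outliers injected per outcome (< n/10).
#' @param outlierMagnitude displacement in robust deviations (MAD units).
#' @param nMissingOutcomeRows subjects with all three outcomes missing
#'   (nucleic-acid sample unavailable); default 5.
#' @param covariateParams list of covariate moments: age mean/sd (years),
#'   probability female, BMI mean/sd (kg/m²), dyslipidemia and statin
#'   prevalences, leisure-time physical activity mean/sd (kcal/day).
#' @return a validated `cohort_config` list.
#' @seealso [simulateCohort()]
#' @export
cohortConfig <- function(nSubjects = 54,
                         classBlockRho = 0.5,
                         logScaleMedians = NULL,
                         logSd = 0.25,
                         totalNoiseSd = 0.03,
                         trueWeights = NULL,
                         targetR = c(tl = 0.347, tert = 0.316, wrap53 = 0.379),
                         outcomeLocation = c(tl = 0.76, tert = log10(8.57), wrap53 = log10(3.46)),
                         outcomeScale = c(tl = (0.88 - 0.63) / (2 * qnorm(0.75)),
                                          tert = log10(11.05 / 7.37) / (2 * qnorm(0.75)),
                                          wrap53 = log10(3.72 / 2.93) / (2 * qnorm(0.75))),
                         missingRateMean = 0.0216,
                         missingRateMax = 0.1111,
                         nOutliersPerOutcome = 1,
                         outlierMagnitude = 10,
                         nMissingOutcomeRows = 5,
                         covariateParams = NULL) {
  if (is.null(logScaleMedians)) {
    logScaleMedians <- c(
      "L-VLDL-P" = 1.8, "M-VLDL-P" = 8, "S-VLDL-P" = 42,       # nmol/L
      "L-LDL-P" = 170, "M-LDL-P" = 440, "S-LDL-P" = 690,       # nmol/L
      "L-HDL-P" = 1.0, "M-HDL-P" = 8.5, "S-HDL-P" = 28)        # µmol/L
  }
  if (is.null(trueWeights)) {
    trueWeights <- list(
      tl     = c("L-LDL-P" = 1, "L-HDL-P" = 1, "HDL-P" = -1, "M-HDL-P" = -1),
      tert   = c("L-HDL-P" = 1, "M-HDL-P" = -1),
      wrap53 = c("S-LDL-P" = 1, "S-HDL-P" = -1, "L-HDL-P" = -1,
                 "S-VLDL-P" = -1, "L-LDL-P" = -1))
  }
  if (is.null(covariateParams)) {
    covariateParams <- list(ageMean = 55, ageSd = 6.25, pFemale = 25 / 54,
                            bmiMean = 28.86, bmiSd = 2.55,
                            pDyslipidemia = 0.5, pStatins = 5 / 54,
                            paMean = 347.40, paSd = 145.33)
  }
  if (nSubjects < 10) stop("nSubjects must be at least 10")
  if (abs(classBlockRho) >= 1) stop("classBlockRho must lie in (-1, 1)")
  subclassNames <- unlist(lapply(lipoproteinClassTotals(), lipoproteinSubclasses))
  if (!setequal(names(logScaleMedians), subclassNames))
    stop("logScaleMedians must name the 9 size subclasses")
  if (any(logScaleMedians <= 0)) stop("medians must be strictly positive")
  if (!(missingRateMean >= 0 && missingRateMean <= missingRateMax &&
        missingRateMax < 0.20))
    stop("need 0 <= missingRateMean <= missingRateMax < 0.20")
  targetR <- targetR[outcomeNames()]
  if (anyNA(targetR) || any(targetR < 0) || any(targetR >= 1))
    stop("targetR must be in [0, 1) for each outcome")
  for (o in outcomeNames()) {
    w <- trueWeights[[o]]
    if (!is.null(w)) {
      if (!all(names(w) %in% lipoproteinVocabulary()))
        stop("trueWeights names must be lipoprotein vocabulary names")
      k <- sum(w != 0)
      if (k < 1 || k > 12)
        stop("trueWeights must have between 1 and 12 nonzero entries per outcome")
    } else if (targetR[[o]] > 0) {
      stop("an outcome with targetR > 0 needs nonzero trueWeights")
    }
  }
  if (nOutliersPerOutcome >= nSubjects / 10)
    stop("nOutliersPerOutcome must be below n/10")
  if (nMissingOutcomeRows > 0.2 * nSubjects)
    stop("nMissingOutcomeRows would exceed 20% outcome missingness")
  structure(list(nSubjects = nSubjects, classBlockRho = classBlockRho,
                 logScaleMedians = logScaleMedians[subclassNames], logSd = logSd,
                 totalNoiseSd = totalNoiseSd, trueWeights = trueWeights,
                 targetR = targetR, outcomeLocation = outcomeLocation,
                 outcomeScale = outcomeScale,
                 missingRateMean = missingRateMean,
                 missingRateMax = missingRateMax,
                 nOutliersPerOutcome = nOutliersPerOutcome,
                 outlierMagnitude = outlierMagnitude,
                 nMissingOutcomeRows = nMissingOutcomeRows,
                 covariateParams = covariateParams),
            class = "cohort_config")
}

# Draw a 3-variable equicorrelated Gaussian block (log scale).
rBlock <- function(n, mu, sd, rho) {
  S <- matrix(rho, 3, 3); diag(S) <- 1
  L <- chol(S)
  z <- matrix(stats::rnorm(n * 3), n, 3) %*% L
  sweep(sweep(z, 2, sd, "*"), 2, mu, "+")
}

#' Simulate a lipoprotein/telomere cohort
#'
#' Generates a complete cohort, builds the outcomes from a sparse linear
#' signal on the rank-normal lipoprotein scale with Gaussian noise scaled so
#' the population correlation with the true score equals `targetR`, then
#' injects missing-completely-at-random lipoprotein cells, whole-row outcome
#' missingness, and gross outcome outliers, per the configuration.
#' Deterministic given `(config, seed)`.
#'
#' @param config a [cohortConfig()].
#' @param seed integer master seed; substreams for concentrations, outcomes,
#'   covariates, missingness and outliers are derived from it.
#' @return a \linkS4class{LipoproteinCohort}; `metadata()` records the
#'   config, seed, the injected outlier positions and the missingness mask.
#' @examples
#' coh <- simulateCohort(cohortConfig(), seed = 1)
#' coh
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$nSubjects
  voc <- lipoproteinVocabulary()

  conc <- withSeed(deriveSeed(seed, 11), {
    m <- matrix(NA_real_, n, 12, dimnames = list(NULL, voc))
    for (tot in lipoproteinClassTotals()) {
      sub <- lipoproteinSubclasses(tot)
      lg <- rBlock(n, mu = log(config$logScaleMedians[sub]),
                   sd = rep(config$logSd, 3), rho = config$classBlockRho)
      m[, sub] <- exp(lg)
      m[, tot] <- rowSums(m[, sub]) *
        exp(stats::rnorm(n, 0, config$totalNoiseSd))
    }
    m
  })

  Z <- apply(conc, 2, inverseNormalTransform)
  ys <- withSeed(deriveSeed(seed, 13), {
    out <- list()
    for (o in outcomeNames()) {
      w <- config$trueWeights[[o]]
      r <- config$targetR[[o]]
      latent <- if (is.null(w) || all(w == 0) || r == 0) {
        stats::rnorm(n)
      } else {
        s <- as.vector(Z[, names(w), drop = FALSE] %*% w)
        s <- (s - mean(s)) / stats::sd(s)
        r * s + sqrt(1 - r^2) * stats::rnorm(n)
      }
      v <- config$outcomeLocation[[o]] + config$outcomeScale[[o]] * latent
      # tert/wrap53 carry their signal on the log10 analysis scale
      out[[o]] <- if (o == "tl") pmax(v, 0.01) else 10^v
    }
    out
  })

  cp <- config$covariateParams
  cov <- withSeed(deriveSeed(seed, 17), data.frame(
    age = pmin(pmax(round(stats::rnorm(n, cp$ageMean, cp$ageSd)), 25), 65),
    sex = stats::rbinom(n, 1, cp$pFemale),
    bmi = pmin(pmax(stats::rnorm(n, cp$bmiMean, cp$bmiSd), 18), 34.9),
    dyslipidemia = stats::rbinom(n, 1, cp$pDyslipidemia),
    statins = stats::rbinom(n, 1, cp$pStatins),
    leisure_pa = pmax(stats::rnorm(n, cp$paMean, cp$paSd), 0)))

  if (config$nMissingOutcomeRows > 0) {
    drop <- withSeed(deriveSeed(seed, 19),
                     sample.int(n, config$nMissingOutcomeRows))
    for (o in outcomeNames()) ys[[o]][drop] <- NA_real_
  }

  cd <- DataFrame(cov, tl = ys$tl, tert = ys$tert, wrap53 = ys$wrap53)
  ids <- sprintf("S%03d", seq_len(n))
  rownames(cd) <- ids
  cohort <- methods::new("LipoproteinCohort", SummarizedExperiment(
    assays = list(concentrations = t(`rownames<-`(conc, ids))),
    colData = cd,
    metadata = list(config = config, seed = seed)))

  cohort <- injectMissing(cohort, config$missingRateMean,
                          config$missingRateMax, seed = deriveSeed(seed, 23))
  injectOutliers(cohort, config$nOutliersPerOutcome,
                 config$outlierMagnitude, seed = deriveSeed(seed, 29))
}

#' Inject missing-completely-at-random lipoprotein cells
#'
#' Masks `round(meanRate * n * 12)` lipoprotein cells uniformly at random,
#' never letting any single variable exceed `floor(maxRate * n)` missing
#' cells. Positions are independent of the data values (MCAR).
#'
#' @param cohort a \linkS4class{LipoproteinCohort}.
#' @param meanRate,maxRate mean and per-variable cap of the missing fraction,
#'   both in \[0, 0.2), `meanRate <= maxRate`.
#' @param seed integer seed.
#' @return the cohort with masked cells; the mask is appended to
#'   `metadata()$missingMask`.
#' @export
injectMissing <- function(cohort, meanRate, maxRate, seed = 1) {
  stopifnot(is(cohort, "LipoproteinCohort"))
  if (!(meanRate >= 0 && meanRate <= maxRate && maxRate < 0.20))
    stop("need 0 <= meanRate <= maxRate < 0.20")
  m <- assay(cohort, "concentrations")  # 12 x n
  p <- nrow(m); n <- ncol(m)
  total <- round(meanRate * n * p)
  if (total == 0) return(cohort)
  cap <- floor(maxRate * n)
  cells <- withSeed(seed, sample.int(n * p))  # column-major order over 12 x n
  taken <- 0L
  perVar <- integer(p)
  mask <- matrix(FALSE, p, n)
  for (cell in cells) {
    v <- (cell - 1L) %% p + 1L
    s <- (cell - 1L) %/% p + 1L
    if (perVar[v] < cap && !is.na(m[v, s])) {
      mask[v, s] <- TRUE
      perVar[v] <- perVar[v] + 1L
      taken <- taken + 1L
      if (taken >= total) break
    }
  }
  m[mask] <- NA_real_
  assay(cohort, "concentrations") <- m
  metadata(cohort)$missingMask <- mask
  methods::validObject(cohort)
  cohort
}

#' Inject gross outcome outliers
#'
#' For each outcome, displaces `kPerOutcome` randomly chosen observed values
#' to median + `magnitude` robust deviations (MAD units), so a downstream
#' robust 99th-percentile screen flags exactly these positions. Displaced
#' positions are recorded in `metadata()$injectedOutliers` for test oracles.
#'
#' @param cohort a \linkS4class{LipoproteinCohort}.
#' @param kPerOutcome outliers per outcome (must be < n/10; 0 is a no-op).
#' @param magnitude displacement in MAD units (default 10).
#' @param seed integer seed.
#' @return the modified cohort.
#' @export
injectOutliers <- function(cohort, kPerOutcome, magnitude = 10, seed = 1) {
  stopifnot(is(cohort, "LipoproteinCohort"))
  n <- ncol(cohort)
  if (kPerOutcome >= n / 10) stop("kPerOutcome must be below n/10")
  if (kPerOutcome == 0) return(cohort)
  cd <- colData(cohort)
  positions <- withSeed(seed, {
    pos <- list()
    for (o in outcomeNames()) {
      v <- cd[[o]]
      obs <- which(!is.na(v))
      idx <- obs[sample.int(length(obs), kPerOutcome)]
      med <- stats::median(v, na.rm = TRUE)
      madv <- stats::mad(v, na.rm = TRUE)
      v[idx] <- med + magnitude * madv
      cd[[o]] <- v
      pos[[o]] <- idx
    }
    pos
  })
  colData(cohort) <- cd
  metadata(cohort)$injectedOutliers <- positions
  methods::validObject(cohort)
  cohort
}
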