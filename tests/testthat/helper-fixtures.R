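# Shared fixtures: everything is generated in code at test time.

# Cohort config without missingness/outliers, for tests that need clean data.
cleanConfig <- function(missingRateMean = 0, nOutliersPerOutcome = 0,
                        nMissingOutcomeRows = 0, ...) {
  cohortConfig(missingRateMean = missingRateMean,
               nOutliersPerOutcome = nOutliersPerOutcome,
               nMissingOutcomeRows = nMissingOutcomeRows, ...)
}

# Small bootstrap count keeps LOOCV unit tests fast; acceptance tests set
# their own.
fastLasso <- function(seed = 1, nBoot = 3, ...) {
  lassoConfig(nBoot = nBoot, seed = seed, ...)
}

# Rank-normal design + response from a clean cohort, for lasso-level tests.
cohortDesign <- function(seed = 1, outcome = "tl", config = cleanConfig()) {
  coh <- simulateCohort(config, seed = seed)
  X <- apply(concentrationMatrix(coh), 2, inverseNormalTransform)
  rownames(X) <- colnames(coh)
  list(X = X, y = SummarizedExperiment::colData(coh)[[outcome]], cohort = coh)
}

# The default per-fold seed streams used by runLOOCV, for tests that need to
# permute folds together with their subjects.
deriveSeedForTest <- function(seed, n) {
  LipoProfile:::deriveSeed(seed, 1000 + seq_len(n))
}

# Build a CoefficientTrace directly (for stability-selection arithmetic).
traceFromMatrix <- function(coefs, heldout = rep(0, nrow(coefs))) {
  methods::new("CoefficientTrace", coefs = coefs,
               intercepts = rep(0, nrow(coefs)),
               lambdas = rep(0.1, nrow(coefs)), heldout = heldout,
               subjects = as.character(seq_len(nrow(coefs))), outcome = "y")
}
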