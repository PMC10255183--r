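test_that("inverse normal transform matches the Blom closed form", {
  expect_equal(inverseNormalTransform(c(10, 20, 30)),
               qnorm((c(1, 2, 3) - 3 / 8) / 3.25))
  expect_equal(round(inverseNormalTransform(c(10, 20, 30)), 4),
               c(-0.8694, 0, 0.8694))
  # middle element of an odd-length tie-free vector sits at the median rank
  x <- c(5, 1, 9, 2, 14)
  expect_equal(inverseNormalTransform(x)[rank(x) == 3], 0)
  expect_error(inverseNormalTransform(rep(2, 5)), "constant")
  expect_error(inverseNormalTransform(c(1, NA, 3)), "missing")
})

test_that("INT is a monotone function of ranks, invariant to monotone input maps", {
  set.seed(1)
  x <- rlnorm(54)
  z <- inverseNormalTransform(x)
  expect_equal(cor(z, rank(x), method = "spearman"), 1)
  expect_true(all(diff(z[order(x)]) > 0))   # strictly monotone in the ranks
  expect_equal(inverseNormalTransform(log(x)), z)   # same ranks, same output
  expect_equal(inverseNormalTransform(x^3), z)
  xt <- c(x, x[1])                                   # ties map to equal outputs
  zt <- inverseNormalTransform(xt)
  expect_equal(zt[1], zt[length(zt)])
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 0.02)
})

test_that("random-forest imputation respects observed cells and collinearity", {
  set.seed(2)
  m <- cbind(x1 = runif(30, 1, 2))
  m <- cbind(m, x2 = 2 * m[, "x1"])
  full <- m
  m[15, "x2"] <- NA
  out <- rfImpute(m, nTrees = 50, seed = 7)
  expect_identical(out[!is.na(m)], m[!is.na(m)])
  # direct regression oracle on the observed rows
  oracle <- predict(lm(x2 ~ x1, data = as.data.frame(m[-15, ])),
                    newdata = data.frame(x1 = m[15, "x1"]))
  expect_equal(unname(out[15, "x2"]), unname(oracle), tolerance = 0.1)
  expect_equal(unname(out[15, "x2"]), unname(full[15, "x2"]), tolerance = 0.1)
  expect_identical(rfImpute(full), full)  # nothing to impute
  expect_error(rfImpute(cbind(a = c(NA, rep(1, 11)))), "2 columns")
  expect_error(rfImpute(cbind(a = rep(NA_real_, 12), b = 1:12)), "entirely missing")
})

test_that("forest imputation beats mean imputation on cohort missingness", {
  wins <- vapply(1:25, function(s) {
    base <- simulateCohort(cleanConfig(), seed = s)
    truth <- concentrationMatrix(base)
    masked <- concentrationMatrix(injectMissing(base, 0.0216, 0.1111, seed = s + 50))
    hole <- is.na(masked)
    rf <- rfImpute(masked, nTrees = 50, seed = s)
    mi <- masked
    for (j in seq_len(ncol(mi))) mi[hole[, j], j] <- mean(mi[, j], na.rm = TRUE)
    nrmse <- function(imp) sqrt(mean(((imp - truth)[hole])^2)) / sd(truth[hole])
    nrmse(rf) < nrmse(mi)
  }, TRUE)
  expect_gt(mean(wins), 0.5)
})

test_that("robust 99th-percentile screen flags a single gross outlier at n = 54", {
  set.seed(3)
  x <- rnorm(54)
  x[20] <- median(x) + 10 * mad(x)
  expect_identical(detectOutcomeOutliers(x), 20L)
  expect_error(detectOutcomeOutliers(c(rep(1, 53), 2)), "MAD")
  # under an iid null at most one value can strictly exceed the cut-off
  flagged <- vapply(1:50, function(s) {
    length(detectOutcomeOutliers(withr::with_seed(s, rnorm(54))))
  }, 0L)
  expect_true(all(flagged %in% c(0L, 1L)))
})

test_that("log10 transform checks positivity and maps the reference values", {
  expect_equal(log10Transform(10), 1)
  expect_equal(log10Transform(1), 0)
  expect_equal(round(log10Transform(8.57), 4), 0.933)
  expect_equal(log10Transform(c(10, NA)), c(1, NA))
  expect_error(log10Transform(c(3, -1)), "row 2")
})

test_that("chained-equation imputation draws from observed donors only", {
  set.seed(4)
  n <- 54
  P <- cbind(a = rnorm(n), b = rnorm(n))
  Y <- cbind(u = 2 * P[, "a"] + rnorm(n, 0, 0.3),
             v = P[, "b"] - P[, "a"] + rnorm(n, 0, 0.3))
  expect_identical(miceImpute(Y, P), Y)
  Ym <- Y
  Ym[1:5, "u"] <- NA; Ym[c(2, 9), "v"] <- NA
  out <- miceImpute(Ym, P, seed = 5)
  expect_identical(out[!is.na(Ym)], Ym[!is.na(Ym)])
  expect_true(all(out[1:5, "u"] %in% Y[-(1:5), "u"]))     # PMM donor property
  expect_true(all(out[c(2, 9), "v"] %in% Y[-c(2, 9), "v"]))
  expect_error(miceImpute(cbind(u = rep(NA_real_, n)), P), "donors")
})

test_that("whole-row outcome missingness imputes to plausible medians", {
  devs <- vapply(1:25, function(s) {
    d <- cohortDesign(seed = s, config = cleanConfig(nMissingOutcomeRows = 5))
    cd <- SummarizedExperiment::colData(d$cohort)
    Y <- cbind(tl = cd$tl, tert = log10Transform(cd$tert),
               wrap53 = log10Transform(cd$wrap53))
    out <- miceImpute(Y, cbind(covariateMatrix(d$cohort), d$X), seed = s)
    obsMed <- apply(Y, 2, median, na.rm = TRUE)
    max(abs(apply(out, 2, median) - obsMed) / abs(obsMed))
  }, 0)
  expect_lt(mean(devs), 0.15)
})

test_that("preprocessing pipeline is deterministic and keeps all n rows", {
  coh <- simulateCohort(cohortConfig(), seed = 6)
  a <- preprocessCohort(coh, seed = 3)
  b <- preprocessCohort(coh, seed = 3)
  expect_identical(intMatrix(a), intMatrix(b))
  expect_identical(outcomeVector(a, "tert"), outcomeVector(b, "tert"))
  expect_equal(dim(intMatrix(a)), c(54L, 12L))
  for (o in outcomeNames()) {
    expect_length(outcomeVector(a, o), 54)
    expect_false(anyNA(outcomeVector(a, o)))
  }
  expect_true(max(abs(colMeans(intMatrix(a)))) < 1e-8)
  expect_true(all(abs(apply(intMatrix(a), 2, sd) - 1) < 0.02))
})

test_that("a clean cohort passes through with all-observed provenance", {
  coh <- simulateCohort(cleanConfig(), seed = 8)
  ds <- preprocessCohort(coh, seed = 1)
  prov <- S4Vectors::metadata(ds)$provenance
  expect_true(all(prov$lipoproteins == "observed"))
  # the robust screen can still flag at most one extreme draw per outcome
  expect_true(all(colSums(prov$outcomes != "observed") <= 1))
})

test_that("injected outliers are excluded exactly once per outcome then re-imputed", {
  coh <- simulateCohort(cohortConfig(), seed = 9)
  ds <- preprocessCohort(coh, seed = 2)
  pos <- S4Vectors::metadata(coh)$injectedOutliers
  for (o in outcomeNames()) {
    fl <- excludedFlags(ds, o)
    expect_equal(sum(fl), 1)
    expect_true(fl[pos[[o]]])
    expect_false(anyNA(outcomeVector(ds, o)))
  }
})

test_that("INT improves a normality score on skewed inputs", {
  coh <- simulateCohort(cleanConfig(), seed = 10)
  ds <- preprocessCohort(coh, seed = 1)
  raw <- concentrationMatrix(coh); z <- intMatrix(ds)
  w_raw <- apply(raw, 2, function(v) shapiro.test(v)$statistic)
  w_int <- apply(z, 2, function(v) shapiro.test(v)$statistic)
  expect_true(all(w_int >= w_raw))
})
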