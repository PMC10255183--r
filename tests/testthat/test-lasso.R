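test_that("lambda path starts at the closed-form entry point", {
  set.seed(1)
  n <- 54
  x <- as.vector(scale(rnorm(n)))        # exact unit sample SD
  y <- 2 + 3 * x                          # corr 1, SD(y) = 3
  g <- lambdaPath(cbind(x = x), y, nLambda = 50)
  expect_equal(g[1], sd(y) * (n - 1) / n)
  expect_length(g, 50)
  expect_true(all(diff(g) < 0))
  expect_error(lambdaPath(cbind(x = x), rep(1, n)), "orthogonal")
  expect_error(lambdaPath(cbind(x = x, z = rep(1, n)), y), "zero-variance")
  # fit at the entry point is exactly the null model
  fit <- fitLasso(cbind(x = x, z = rnorm(n)), y, g[1])
  expect_equal(unname(fit$coefficients), c(0, 0))
  expect_equal(fit$intercept, mean(y))
})

test_that("lasso at lambda = 0 matches the normal-equations OLS solution", {
  set.seed(2)
  n <- 50; p <- 8
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- X %*% rnorm(p) + rnorm(n)
  fit <- fitLasso(X, y, 0)
  D <- cbind(1, X)
  beta_ols <- solve(crossprod(D), crossprod(D, y))
  expect_lt(max(abs(c(fit$intercept, fit$coefficients) - beta_ols)), 1e-5)
})

test_that("orthonormal-design lasso equals coordinate-wise soft-thresholding", {
  set.seed(3)
  n <- 40; p <- 5
  M <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Q <- qr.Q(qr(M)) * sqrt(n)   # centered columns with X'X = n I
  colnames(Q) <- paste0("q", 1:p)
  y <- Q %*% c(1, -0.5, 0.2, 0, 0) + rnorm(n, 0, 0.5)
  for (lam in c(0.05, 0.3, 0.8)) {
    fit <- fitLasso(Q, y, lam)
    z <- as.vector(crossprod(Q, y - mean(y))) / n
    oracle <- sign(z) * pmax(abs(z) - lam, 0)
    expect_lt(max(abs(fit$coefficients - oracle)), 1e-5)
  }
})

test_that("sparsity is non-increasing in the penalty along the path", {
  for (s in 1:5) {
    set.seed(s)
    n <- 45; p <- 10
    X <- matrix(rnorm(n * p), n, p)
    y <- X[, 1:3] %*% c(2, -1, 1) + rnorm(n)
    g <- lambdaPath(X, y, nLambda = 25)
    nz <- vapply(g, function(l) sum(fitLasso(X, y, l)$coefficients != 0), 0L)
    expect_true(all(diff(nz) >= 0))  # grid decreasing -> sparsity non-increasing
  }
})

test_that("bootstrap tuning shrinks noise hard and signal lightly", {
  n <- 40; p <- 6
  pickNoise <- vapply(1:60, function(s) {
    set.seed(s)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    g <- lambdaPath(X, y, nLambda = 40)
    tuneLambdaBootstrap(X, y, g, nBoot = 8, seed = s) >= median(g)
  }, TRUE)
  expect_gte(mean(pickNoise), 0.8)
  pickSignal <- vapply(1:20, function(s) {
    set.seed(s + 500)
    X <- matrix(rnorm(n * p), n, p)
    y <- as.vector(X[, 1] * 2)            # noiseless single-predictor signal
    g <- lambdaPath(X, y, nLambda = 40)
    tuneLambdaBootstrap(X, y, g, nBoot = 8, seed = s) <= quantile(g, 0.1)
  }, TRUE)
  expect_gte(mean(pickSignal), 0.9)
  g <- lambdaPath(matrix(rnorm(40 * 6), 40), rnorm(40), nLambda = 20)
  X <- matrix(rnorm(40 * 6), 40); y <- rnorm(40)
  expect_identical(tuneLambdaBootstrap(X, y, g, nBoot = 1, seed = 4)[1],
                   tuneLambdaBootstrap(X, y, g, nBoot = 1, seed = 4)[1])
})

test_that("LOOCV recovers a noiseless sparse signal almost perfectly", {
  d <- cohortDesign(seed = 1)
  w <- c("S-VLDL-P" = 1, "L-LDL-P" = 1, "M-HDL-P" = -1)
  y <- as.vector(d$X[, names(w)] %*% w)
  tr <- runLOOCV(d$X, y, fastLasso(seed = 2), outcome = "tl")
  expect_gt(cor(y, heldoutPredictions(tr)), 0.99)
  expect_equal(nrow(coefMatrix(tr)), 54)
})

test_that("held-out predictions never leak the left-out outcome", {
  d <- cohortDesign(seed = 2)
  cfg <- fastLasso(seed = 3)
  seeds <- deriveSeedForTest(cfg$seed, 54)
  tr <- runLOOCV(d$X, d$y, cfg, foldSeeds = seeds, outcome = "tl")
  for (i in c(1, 27, 54)) {
    yc <- d$y
    yc[i] <- yc[i] + 100           # corrupt subject i's outcome
    trc <- runLOOCV(d$X, yc, cfg, foldSeeds = seeds, outcome = "tl")
    expect_equal(heldoutPredictions(trc)[[i]], heldoutPredictions(tr)[[i]])
  }
})

test_that("row order is irrelevant when fold seeds follow their subjects", {
  d <- cohortDesign(seed = 3)
  cfg <- fastLasso(seed = 5)
  seeds <- deriveSeedForTest(cfg$seed, 54)
  tr <- runLOOCV(d$X, d$y, cfg, foldSeeds = seeds, outcome = "tl")
  set.seed(9); perm <- sample(54)
  trp <- runLOOCV(d$X[perm, ], d$y[perm], cfg, foldSeeds = seeds[perm],
                  outcome = "tl")
  a <- heldoutPredictions(tr); b <- heldoutPredictions(trp)
  expect_equal(b[names(a)], a)
})

test_that("permuted outcomes yield no spuriously positive held-out correlation", {
  d <- cohortDesign(seed = 4)
  rs <- vapply(1:25, function(k) {
    yp <- withr::with_seed(k, sample(d$y))
    tr <- runLOOCV(d$X, yp, fastLasso(seed = k, nBoot = 2), outcome = "tl")
    cor(yp, heldoutPredictions(tr))
  }, 0)
  # a null model's held-out predictions are anti-correlated with the outcome
  # (each fold's intercept is the mean without the held-out subject), so the
  # permutation-null mean is at or below zero, never positive
  expect_lte(mean(rs), 0)
  expect_lt(mean(rs > 0.35), 0.1)
})

test_that("adjusted run with no covariates reduces to the unadjusted run", {
  d <- cohortDesign(seed = 5)
  cfg <- fastLasso(seed = 7)
  adj <- runAdjusted(d$X, d$y, NULL, cfg)
  tr <- runLOOCV(d$X, d$y, cfg, outcome = "y")
  expect_equal(coefMatrix(adj$trace), coefMatrix(tr))
  expect_equal(heldoutPredictions(adj$trace), heldoutPredictions(tr))
})

test_that("unpenalized covariates stay in the model and absorb a confounder", {
  d <- cohortDesign(seed = 6)
  cfg <- fastLasso(seed = 11)
  # planted confounder drives both one lipoprotein and the outcome
  diffs <- vapply(1:8, function(s) {
    set.seed(s * 13)
    conf <- rnorm(54)
    X <- d$X
    X[, "M-HDL-P"] <- as.vector(scale(X[, "M-HDL-P"] + 1.5 * conf))
    y <- 0.5 * conf + rnorm(54, 0, 0.5)
    un <- runLOOCV(X, y, cfg, outcome = "y")
    ad <- runAdjusted(X, y, cbind(conf = conf), cfg)
    unCnt <- sum(coefMatrix(un)[, "M-HDL-P"] != 0)
    adCnt <- sum(coefMatrix(ad$lipoTrace)[, "M-HDL-P"] != 0)
    unCnt - adCnt
  }, 0)
  expect_gte(mean(diffs), 0)
  expect_error(runAdjusted(d$X, d$y, cbind(a = rep(1, 54)), cfg), "collinear")
})

test_that("covariate-adjusted design reports lipoprotein columns only", {
  d <- cohortDesign(seed = 7)
  covm <- covariateMatrix(d$cohort)
  adj <- runAdjusted(d$X, d$y, covm, fastLasso(seed = 2))
  expect_identical(colnames(coefMatrix(adj$lipoTrace)), colnames(d$X))
  expect_identical(adj$model@variables, colnames(d$X))
  expect_equal(ncol(coefMatrix(adj$trace)), ncol(d$X) + ncol(covm))
  # unpenalized covariates are never shrunk away
  covCoefs <- coefMatrix(adj$trace)[, colnames(covm)]
  expect_true(all(covCoefs != 0))
})
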