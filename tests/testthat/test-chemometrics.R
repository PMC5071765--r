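test_that("critical correlation matches the t-inversion oracle", {
  # oracle: invert the t CDF numerically for the two-tailed critical t,
  # then map to r
  oracle <- function(alpha, n) {
    tc <- uniroot(function(t) pt(t, n - 2) - (1 - alpha / 2), c(0, 100),
                  tol = 1e-12)$root
    sqrt(tc^2 / (tc^2 + n - 2))
  }
  expect_equal(round(criticalR(0.05, 11), 3), 0.602)
  expect_equal(round(criticalR(0.05, 10), 3), 0.632)
  for (n in c(5, 10, 11, 20, 50))
    for (alpha in c(0.01, 0.05, 0.1))
      expect_equal(criticalR(alpha, n), oracle(alpha, n), tolerance = 1e-9)
  # limits and monotonicity
  expect_lt(criticalR(0.999, 11), 0.01)
  ns <- 4:30
  expect_true(all(diff(sapply(ns, function(n) criticalR(0.05, n))) < 0))
  expect_gt(criticalR(0.01, 11), criticalR(0.05, 11))
  expect_error(criticalR(0.05, 2), ">= 3")
})

test_that("NIPALS first component matches the eigen-oracle", {
  # w1 must be the dominant eigenvector of X'yy'X (normalized)
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(5 * 8), 5, 8)
    y <- c(-1, -1, 1, 1, 1)
    Xc <- scale(X, scale = FALSE)
    yc <- y - mean(y)
    m <- fitPlsda(X, y, nComponents = 1)
    M <- crossprod(Xc, yc) %*% crossprod(yc, Xc)
    ev <- eigen(M, symmetric = TRUE)$vectors[, 1]
    w <- m@weights[, 1]
    expect_equal(abs(sum(w * ev)), 1, tolerance = 1e-8)
  }
})

test_that("rank-1 class-aligned data is explained exactly by one component", {
  set.seed(1)
  y <- rep(c(-1, 1), each = 4)
  p <- rnorm(30)
  X <- (y - mean(y)) %*% t(p)
  m <- fitPlsda(X, y, nComponents = 1)
  expect_equal(m@r2y, 1, tolerance = 1e-10)
  pl <- m@loadings[, 1]
  expect_equal(abs(cor(pl, p)), 1, tolerance = 1e-10)
})

test_that("single-class y is an error and excess components truncate", {
  X <- matrix(rnorm(40), 8, 5)
  expect_error(fitPlsda(X, rep(1, 8)), "two classes")
  expect_warning(fitPlsda(X, rep(c(-1, 1), 4), nComponents = 8),
                 "truncat")
})

test_that("OPLS-DA with no orthogonal variation reduces to PLS-DA", {
  set.seed(2)
  y <- rep(c(-1, 1), each = 5)
  p <- rnorm(40)
  X <- (y - mean(y)) %*% t(p)          # every direction class-covarying
  pls <- fitPlsda(X, y, nComponents = 1)
  opls <- fitOplsda(X, y, nOrtho = 1, cv = FALSE)
  expect_equal(abs(opls@predictiveScores), abs(pls@scores[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(opls@nOrtho, 0L)    # nothing orthogonal to remove
})

test_that("structured y-orthogonal variation leaves predictive loadings intact", {
  set.seed(3)
  n <- 12
  y <- rep(c(-1, 1), each = n / 2)
  signal <- (y - mean(y)) %*% t(rnorm(50))
  noise <- matrix(rnorm(n * 50, sd = 0.01), n, 50)
  Xclean <- signal + noise
  to <- rep(c(1, -1), n / 2)           # orthogonal to y by construction
  to <- to - mean(to)
  expect_equal(sum(to * y), 0)
  Xdirty <- Xclean + 5 * to %*% t(rnorm(50))
  mc <- fitOplsda(Xclean, y, nOrtho = 1, cv = FALSE)
  md <- fitOplsda(Xdirty, y, nOrtho = 1, cv = FALSE)
  # compare loadings up to overall sign
  pc <- mc@predictiveLoadings; pd <- md@predictiveLoadings
  expect_gt(abs(cor(pc, pd)), 0.99)
  expect_gt(abs(cor(mc@predictiveScores, md@predictiveScores)), 0.99)
})

test_that("nOrtho at or above n - 2 is rejected", {
  X <- matrix(rnorm(60), 6, 10)
  y <- rep(c(-1, 1), 3)
  expect_error(fitOplsda(X, y, nOrtho = 4, cv = FALSE), "n - 2")
})

test_that("venetian folds interleave and stratify when needed", {
  y <- rep(c(-1, 1), each = 10)
  expect_identical(venetianFolds(y, 5), rep(1:5, 4))
  # alternating classes with two folds would put one class per training
  # split; stratified reassignment must repair that
  ya <- rep(c(-1, 1), 4)
  expect_warning(f <- venetianFolds(ya, 2), "stratified")
  for (k in unique(f))
    expect_length(unique(ya[f != k]), 2)
})

test_that("Q2 is one for perfect prediction and near zero for the mean", {
  # perfect: strong rank-1 signal, no noise
  y <- rep(c(-1, 1), each = 10)
  X <- (y - mean(y)) %*% t(rnorm(25))
  cv <- crossValidateQ2(X, y, nFolds = 5, method = "oplsda", nOrtho = 0)
  expect_equal(cv$q2, 1, tolerance = 1e-8)
  # mean prediction: PRESS equals SSY up to fold-mean jitter
  press <- sum((y - mean(y))^2)
  expect_equal(1 - press / cv$ssy, 0)
  # pure noise: Q2 at or below zero within sampling noise
  set.seed(4)
  q2s <- replicate(10, {
    Xn <- matrix(rnorm(20 * 30), 20, 30)
    crossValidateQ2(Xn, sample(y), nFolds = 5, nOrtho = 1)$q2
  })
  expect_lt(median(q2s), 0.08)
})

test_that("CV-ANOVA gives p = 1 when the model beats nothing", {
  fake <- structure(list(q2 = 0, press = 10, ssy = 10, n = 20,
                         dfModel = 2L), class = "q2cv")
  expect_identical(cvAnova(fake), 1)
  worse <- structure(list(q2 = -0.2, press = 12, ssy = 10, n = 20,
                          dfModel = 2L), class = "q2cv")
  expect_identical(cvAnova(worse), 1)
})

test_that("CV-ANOVA is significant for strong separation, calibrated under the null", {
  d <- mimicDesign(seed = 1, nPerGroup = 5)
  bm <- buildBinMatrix(simulateSpectra(d))
  m <- fitOplsda(bm)
  expect_lt(cvAnovaP(m), 0.05)
  # null: no planted effects; the false-positive rate over 20 seeds
  # stays within binomial noise of the nominal 5%
  # (P[X >= 5 | n = 20, p = 0.05] < 0.003)
  hits <- 0L
  for (s in 1:20) {
    dn <- syntheticDesign(effectMap = defaultEffectMap(0), nPerGroup = 5,
                          seed = s)
    bmn <- buildBinMatrix(simulateSpectra(dn))
    hits <- hits + (cvAnovaP(fitOplsda(bmn)) < 0.05)
  }
  expect_lte(hits, 4L)
})

test_that("q2 never exceeds r2y and scores stay orthogonal", {
  for (s in 1:5) {
    d <- mimicDesign(seed = s, nPerGroup = 5)
    m <- fitOplsda(buildBinMatrix(simulateSpectra(d)))
    expect_lte(q2(m), r2y(m) + 1e-8)
    t <- predictiveScores(m); To <- orthoScores(m)
    for (j in seq_len(ncol(To)))
      expect_lt(abs(sum(t * To[, j])) /
                  sqrt(sum(t^2) * sum(To[, j]^2)), 1e-8)
  }
})

test_that("coefficient loadings: perfect bin, flat bin, cutoff calibration", {
  d <- mimicDesign(seed = 2, nPerGroup = 5)
  bm <- buildBinMatrix(simulateSpectra(d))
  m <- fitOplsda(bm)
  X <- binValues(bm)
  # append a bin equal to the scores and a flat bin
  X2 <- cbind(X, m@predictiveScores, 1)
  m2 <- m
  cl <- coefficientLoadings(m2, X2)
  expect_equal(cl@r[ncol(X) + 1], 1, tolerance = 1e-12)
  expect_true((ncol(X) + 1) %in% significantBins(cl))
  expect_identical(cl@r[ncol(X) + 2], 0)
  expect_identical(cl@zeroVarianceBins, ncol(X) + 2L)

  # a pure-noise bin correlated against a fixed score vector stays
  # below the 0.602 cutoff in about 95% of draws at n = 11
  set.seed(11)
  t11 <- rnorm(11)
  rs <- replicate(1000, abs(cor(rnorm(11), t11)))
  expect_gte(mean(rs <= 0.602), 0.93)
})

test_that("planted biomarker directions carry the right sign of r", {
  d <- mimicDesign(seed = 1)
  bm <- buildBinMatrix(simulateSpectra(d))
  m <- fitOplsda(bm)
  cl <- coefficientLoadings(m, bm)
  ctr <- binCenters(bm)
  succ <- which(abs(ctr - 2.41) < 0.01)   # succinate, planted up
  leu <- which(abs(ctr - 0.96) < 0.01)    # leucine, planted down
  expect_gt(max(cl@r[succ]), 0)
  expect_lt(min(cl@r[leu]), 0)
})

test_that("metabolite calling maps bins to names, directions and unassigned regions", {
  cl <- new("CoefficientLoadings", r = c(0.9, -0.7, 0.1, 0.8),
            rCrit = 0.602, alpha = 0.05,
            significantBins = c(1L, 2L, 4L),
            binCenters = c(1.4775, 0.9625, 3.0025, 6.5025),
            zeroVarianceBins = integer())
  lib <- defaultMetaboliteLibrary()
  calls <- callSignificantMetabolites(cl, lib)
  expect_identical(calls$metabolite[1], "alanine")   # |r| = 0.9
  expect_identical(calls$direction[1], "up")
  expect_match(calls$metabolite[2], "unassigned region")  # |r| = 0.8
  expect_identical(calls$metabolite[3], "leucine")   # |r| = 0.7
  expect_identical(calls$direction[3], "down")
  # no significant bins -> empty table
  clEmpty <- new("CoefficientLoadings", r = rep(0, 4), rCrit = 0.602,
                 alpha = 0.05, significantBins = integer(),
                 binCenters = cl@binCenters, zeroVarianceBins = integer())
  expect_identical(nrow(callSignificantMetabolites(clEmpty, lib)), 0L)
})

test_that("first PLS component agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(8)
  X <- matrix(rnorm(10 * 20), 10, 20)
  y <- rep(c(-1, 1), each = 5)
  X[y == 1, 1:5] <- X[y == 1, 1:5] + 2
  m <- fitPlsda(X, y, nComponents = 1)
  ref <- mixOmics::pls(X, as.numeric(y), ncomp = 1, scale = FALSE,
                       mode = "regression")
  wRef <- ref$loadings$X[, 1] / sqrt(sum(ref$loadings$X[, 1]^2))
  expect_equal(abs(sum(m@weights[, 1] * wRef)), 1, tolerance = 1e-6)
})
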