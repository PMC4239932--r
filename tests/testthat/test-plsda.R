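test_that("one component recovers a response carried by a single band", {
  set.seed(21)
  n <- 60; p <- 8
  y <- rep(0:1, n / 2)
  X <- matrix(rnorm(n * p), n, p)
  # make the distractor bands empirically uncorrelated with y, so band 3
  # carries the response exactly
  X <- apply(X, 2L, function(x) stats::residuals(stats::lm(x ~ y)))
  X[, 3] <- y + rnorm(n, sd = 0.01)
  fit <- fitPLS(X, y, 1L)
  b <- abs(plsBeta(fit))
  expect_identical(which.max(b), 3L)
  expect_gt(b[3], 5 * max(b[-3]))
  pred <- sweep(X, 2, fit@xMean) %*% plsBeta(fit) + fit@yMean
  expect_lt(sqrt(mean((pred - y)^2)), 0.05)
})

test_that("random labels produce a near-null model", {
  set.seed(33)
  X <- matrix(rnorm(240 * 10), 240, 10)
  y <- withr::with_seed(1, sample(rep(0:1, 120)))
  fit <- fitPLS(X, y, 1L)
  pred <- sweep(X, 2, fit@xMean) %*% plsBeta(fit) + fit@yMean
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_lt(r2, 0.1)
  # coefficients stay an order of magnitude below the signal case, where
  # the carrier band weight is ~1
  expect_lt(max(abs(plsBeta(fit))), 0.15)
})

test_that("full-rank PLS equals the least-squares solution", {
  set.seed(101)
  for (trial in 1:100) {
    X <- matrix(rnorm(20 * 10), 20, 10)
    y <- as.numeric(rnorm(10) %*% t(X) > 0)
    if (var(y) == 0) next
    fit <- suppressWarnings(fitPLS(X, y, 10L))
    ls <- lsBetaOracle(X, y)
    expect_equal(plsBeta(fit), ls, tolerance = 1e-6)
  }
})

test_that("NIPALS agrees with an independent PLS implementation", {
  set.seed(55)
  X <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(NULL, paste0("b", 1:12)))
  y <- as.numeric(X[, 1] + 0.5 * X[, 7] + rnorm(40, sd = 0.3) > 0)
  k <- 3L
  fit <- fitPLS(X, y, k)
  ref <- mixOmics::pls(X, y, ncomp = k, mode = "regression", scale = FALSE)
  pred <- predict(ref, X)$predict[, 1, k]
  own <- as.numeric(sweep(X, 2, fit@xMean) %*% plsBeta(fit) + fit@yMean)
  expect_equal(own, unname(pred), tolerance = 1e-8)
})

test_that("score vectors are orthogonal and explained variance is monotone", {
  set.seed(77)
  X <- matrix(rnorm(50 * 15), 50, 15)
  y <- as.numeric(rowSums(X[, 1:3]) > 0)
  fit <- fitPLS(X, y, 6L)
  Tm <- fit@scoresX
  G <- crossprod(Tm)
  offDiag <- G - diag(diag(G))
  expect_lt(max(abs(offDiag)) / max(diag(G)), 1e-8)

  # explained X variance is non-decreasing in the component count
  Xc <- sweep(X, 2, fit@xMean)
  total <- sum(Xc^2)
  ev <- vapply(1:6, function(k) {
    approx <- fit@scoresX[, 1:k, drop = FALSE] %*%
      t(fit@loadingsX[, 1:k, drop = FALSE])
    1 - sum((Xc - approx)^2) / total
  }, numeric(1))
  expect_true(all(diff(ev) >= -1e-12))
})

test_that("factor matrices satisfy the stated bilinear structure", {
  set.seed(91)
  X <- matrix(rnorm(30 * 9), 30, 9)
  y <- as.numeric(X[, 2] > 0)
  fit <- fitPLS(X, y, 4L)
  Xc <- sweep(X, 2, fit@xMean)
  expect_equal(Xc, fit@scoresX %*% t(fit@loadingsX) + fit@residualX,
               tolerance = 1e-10)
  # inner relation: B = (T'T)^-1 T'U and G its residual
  B <- solve(crossprod(fit@scoresX), crossprod(fit@scoresX, fit@scoresY))
  expect_equal(fit@innerCoef, B, tolerance = 1e-10)
  expect_equal(fit@innerResidual, fit@scoresY - fit@scoresX %*% B,
               tolerance = 1e-10)
})

test_that("component selection finds a rank-1 signal and reports the curve", {
  set.seed(13)
  n <- 90
  t1 <- rnorm(n)
  X <- outer(t1, rnorm(12)) + matrix(rnorm(n * 12, sd = 1e-4), n, 12)
  y <- as.numeric(t1 > 0)
  curve <- selectComponents(X, y, maxK = 5L, splitSeed = 4L)
  expect_identical(curve@chosen, 1L)
  expect_true(all(curve@values >= 0))

  # a perfectly predictable response drives RMSEV to ~0
  y2 <- 0.3 * t1
  curve2 <- selectComponents(X, y2, maxK = 3L, splitSeed = 4L)
  expect_lt(min(curve2@values), 1e-3)
})

test_that("pure-noise responses never beat the mean predictor by much", {
  set.seed(44)
  worst <- vapply(1:20, function(s) {
    X <- matrix(rnorm(60 * 8), 60, 8)
    y <- sample(rep(0:1, 30))
    curve <- selectComponents(X, y, maxK = 4L, splitSeed = s)
    # RMSEV of predicting the calibration mean on the validation rows
    # is ~0.5 for a balanced 0/1 response
    min(curve@values)
  }, numeric(1))
  expect_gt(mean(worst), 0.5 * 0.9)
})

test_that("score images obey the centering identity and rank crack above specular", {
  scene <- renderScene(smallPhantomConfig("CRACKED", seed = 6))
  ls <- extractSpectra(scene@cube, sceneTruth(scene))
  sampled <- suppressWarnings(sampleSpectra(ls, perClass = 200L, seed = 2L))
  model <- trainPLSDA(sampled, maxK = 8L)

  # a pixel equal to the training mean scores exactly the y mean
  wl <- wavelengths(scene@cube)
  flat <- HyperCube(array(rep(model@xMean,
                              each = 4), c(2, 2, length(wl))), wl)
  expect_equal(as.vector(scoreImage(model, flat)),
               rep(model@yMean, 4), tolerance = 1e-10)

  s <- scoreImage(model, scene@cube)
  tr <- sceneTruth(scene)
  expect_gt(median(s[tr == 2L]), median(s[tr == 4L]))
  expect_gt(mean(s[tr == 2L] >= 0.5), 0.9)

  other <- uniformCube(0.5, wl = seq(1000, 1700, length.out = 7))
  expect_error(scoreImage(model, other), "grid")
})

test_that("binarization is inclusive at the threshold", {
  s <- matrix(c(0.4, 0.5, 0.6, 0.499999), 2, 2)
  b <- binarizeScores(s, 0.5)
  expect_identical(as.vector(b), c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(binarizeScores(matrix(0.4, 3, 3), 0.5)))
})

test_that("beta extrema report carries wavelengths of the largest peaks", {
  scene <- renderScene(smallPhantomConfig("CRACKED", seed = 6))
  ls <- extractSpectra(scene@cube, sceneTruth(scene))
  sampled <- suppressWarnings(sampleSpectra(ls, perClass = 200L, seed = 2L))
  model <- trainPLSDA(sampled, maxK = 8L)
  pk <- betaPeaks(model, 3L)
  expect_identical(nrow(pk), 3L)
  expect_true(all(pk$wavelength %in% wavelengths(model)))
  expect_true(all(abs(pk$beta[1]) >= abs(pk$beta)))
})

test_that("PLS-DA models survive text serialization", {
  scene <- renderScene(smallPhantomConfig("CRACKED", seed = 9))
  ls <- extractSpectra(scene@cube, sceneTruth(scene))
  sampled <- suppressWarnings(sampleSpectra(ls, perClass = 150L, seed = 3L))
  model <- trainPLSDA(sampled, maxK = 5L)
  path <- file.path(withr::local_tempdir(), "model.tsv")
  writePLSDAModel(model, path)
  back <- readPLSDAModel(path)
  expect_equal(back@beta, model@beta, tolerance = 1e-12)
  expect_equal(back@xMean, model@xMean, tolerance = 1e-12)
  expect_identical(back@ncomp, model@ncomp)
  expect_identical(back@positiveLabel, model@positiveLabel)
  s1 <- scoreImage(model, scene@cube)
  s2 <- scoreImage(back, scene@cube)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("degenerate PLS inputs are rejected", {
  X <- matrix(1, 10, 4)
  expect_error(fitPLS(X, rep(0:1, 5), 2L), "zero-variance")
  X2 <- matrix(rnorm(40), 10, 4)
  expect_error(fitPLS(X2, rep(0:1, 5), 12L), "out of range")
  expect_error(selectComponents(X2, rep(0:1, 5), maxK = 0L), "maxK")
})
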