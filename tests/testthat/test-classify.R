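makeFeatures <- function(n, muR, muD, sdR = 0.05, sdD = 1, label) {
  data.frame(sample_id = sprintf("%s%03d", label, seq_len(n)),
             label = label, R = rnorm(n, muR, sdR),
             D = rnorm(n, muD, sdD), stringsAsFactors = FALSE)
}

test_that("the stratified split reproduces the 84/28 protocol", {
  set.seed(1)
  f <- rbind(makeFeatures(112, 0.9, 3, label = "SOUND"),
             makeFeatures(112, 0.5, 18, label = "CRACKED"))
  sp <- splitFeatures(f, fraction = 0.75, seed = 5L)
  expect_equal(as.vector(table(sp$calibration$label)[c("CRACKED", "SOUND")]),
               c(84L, 84L))
  expect_equal(as.vector(table(sp$validation$label)[c("CRACKED", "SOUND")]),
               c(28L, 28L))
  # disjoint and exhaustive
  expect_identical(sort(c(sp$calibration$sample_id, sp$validation$sample_id)),
                   sort(f$sample_id))
  # deterministic
  sp2 <- splitFeatures(f, fraction = 0.75, seed = 5L)
  expect_identical(sp, sp2)

  expect_error(splitFeatures(f, fraction = 1.0, seed = 1L), "empty")
  expect_error(splitFeatures(f[f$label == "SOUND", ], seed = 1L),
               "both classes")
})

test_that("1-D LDA places the boundary midway between class means", {
  f <- data.frame(sample_id = as.character(1:4),
                  label = c("SOUND", "SOUND", "CRACKED", "CRACKED"),
                  R = c(0, 1, 4, 5), D = 0, stringsAsFactors = FALSE)
  m <- fitLDA(f, featureNames = "R")
  # decision value crosses zero at x = 2.5
  boundary <- -m@bias / m@weights[["R"]]
  expect_equal(boundary, 2.5, tolerance = 1e-10)
  expect_identical(predictClass(m, data.frame(R = 3)), "CRACKED")
  expect_identical(predictClass(m, data.frame(R = 2)), "SOUND")
})

test_that("LDA weight matches the pooled-scatter closed form", {
  set.seed(42)
  for (trial in 1:25) {
    n <- 40
    f <- rbind(makeFeatures(n, 0.8, 5, 0.1, 2, "SOUND"),
               makeFeatures(n, 0.5, 14, 0.12, 3, "CRACKED"))
    m <- fitLDA(f)
    X <- as.matrix(f[, c("R", "D")])
    Xp <- X[f$label == "CRACKED", ]; Xn <- X[f$label == "SOUND", ]
    Sw <- crossprod(sweep(Xp, 2, colMeans(Xp))) +
          crossprod(sweep(Xn, 2, colMeans(Xn)))
    wRef <- solve(Sw) %*% (colMeans(Xp) - colMeans(Xn))
    expect_equal(unname(m@weights), as.numeric(wRef), tolerance = 1e-8)
    bRef <- -sum(wRef * (colMeans(Xp) + colMeans(Xn)) / 2)
    expect_equal(m@bias, bRef, tolerance = 1e-8)
  }
})

test_that("LDA direction agrees with MASS::lda up to scale", {
  set.seed(7)
  f <- rbind(makeFeatures(60, 0.85, 4, 0.08, 1.5, "SOUND"),
             makeFeatures(60, 0.55, 13, 0.1, 2.5, "CRACKED"))
  m <- fitLDA(f)
  ref <- MASS::lda(as.matrix(f[, c("R", "D")]), grouping = f$label)
  ratio <- m@weights / as.numeric(ref$scaling)
  expect_equal(ratio[[1]] / ratio[[2]], 1, tolerance = 1e-6)
})

test_that("LDA with identity scatter points along the mean difference", {
  # two symmetric pairs around each mean give Sw proportional to I
  f <- data.frame(sample_id = as.character(1:8),
                  label = rep(c("SOUND", "CRACKED"), each = 4),
                  R = c(0 + c(1, -1, 0, 0), 3 + c(1, -1, 0, 0)),
                  D = c(0 + c(0, 0, 1, -1), 4 + c(0, 0, 1, -1)),
                  stringsAsFactors = FALSE)
  m <- fitLDA(f)
  expect_equal(m@weights[["R"]] / m@weights[["D"]], 3 / 4,
               tolerance = 1e-10)
})

test_that("LDA predictions are invariant to affine feature transforms", {
  set.seed(19)
  f <- rbind(makeFeatures(50, 0.8, 5, 0.1, 2, "SOUND"),
             makeFeatures(50, 0.5, 14, 0.1, 2, "CRACKED"))
  test <- rbind(makeFeatures(20, 0.75, 6, 0.15, 3, "SOUND"),
                makeFeatures(20, 0.55, 13, 0.15, 3, "CRACKED"))
  p0 <- predictClass(fitLDA(f), test)
  for (trial in 1:5) {
    A <- matrix(rnorm(4), 2, 2)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(4), 2, 2)
    shift <- rnorm(2)
    tf <- function(d) {
      Z <- as.matrix(d[, c("R", "D")]) %*% t(A)
      d$R <- Z[, 1] + shift[1]; d$D <- Z[, 2] + shift[2]; d
    }
    expect_identical(predictClass(fitLDA(tf(f)), tf(test)), p0)
  }
})

test_that("hard-margin SVM solves the symmetric pair exactly", {
  f <- data.frame(sample_id = as.character(1:4),
                  label = rep(c("SOUND", "CRACKED"), each = 2),
                  R = c(-1, -1, 1, 1), D = c(-0.5, 0.5, -0.5, 0.5),
                  stringsAsFactors = FALSE)
  m <- fitSVM(f, cost = 1e6, standardize = FALSE)
  # boundary R = 0, geometric margin 1
  expect_equal(abs(m@weights[["R"]]) / sqrt(sum(m@weights^2)), 1,
               tolerance = 1e-4)
  expect_equal(m@bias, 0, tolerance = 1e-4)
  expect_equal(m@margin, 1, tolerance = 1e-3)

  # an interior point far from the margin changes nothing
  f2 <- rbind(f, data.frame(sample_id = "extra", label = "CRACKED",
                            R = 5, D = 0, stringsAsFactors = FALSE))
  m2 <- fitSVM(f2, cost = 1e6, standardize = FALSE)
  expect_equal(m2@weights / sqrt(sum(m2@weights^2)),
               m@weights / sqrt(sum(m@weights^2)), tolerance = 1e-4)
  expect_false("extra" %in% f2$sample_id[m2@supportIndex])
})

test_that("SVM matches the brute-force maximum-margin oracle", {
  set.seed(88)
  done <- 0
  while (done < 20) {
    n <- 10
    f <- rbind(makeFeatures(n, 0, 0, 1, 1, "SOUND"),
               makeFeatures(n, 4, 4, 1, 1, "CRACKED"))
    X <- as.matrix(f[, c("R", "D")])
    y <- ifelse(f$label == "CRACKED", 1, -1)
    oracle <- svmOracle2d(X, y)
    if (is.null(oracle) || oracle$margin < 0.3) next  # need clear separation
    done <- done + 1
    m <- fitSVM(f, cost = 1e7, standardize = FALSE)
    wn <- m@weights / sqrt(sum(m@weights^2))
    bn <- m@bias / sqrt(sum(m@weights^2))
    expect_equal(unname(wn), oracle$w, tolerance = 1e-4)
    expect_equal(bn, oracle$b, tolerance = 1e-4)
    expect_equal(m@margin, oracle$margin, tolerance = 1e-4)
  }
})

test_that("the SVM margin beats 1000 random separating hyperplanes", {
  set.seed(5)
  f <- rbind(makeFeatures(15, 0, 0, 0.8, 0.8, "SOUND"),
             makeFeatures(15, 4, 4, 0.8, 0.8, "CRACKED"))
  X <- as.matrix(f[, c("R", "D")])
  y <- ifelse(f$label == "CRACKED", 1, -1)
  m <- fitSVM(f, cost = 1e7, standardize = FALSE)
  for (i in 1:1000) {
    w <- rnorm(2); w <- w / sqrt(sum(w^2))
    b <- runif(1, -8, 8)
    d <- X %*% w + b
    if (all(sign(d) == y) || all(sign(d) == -y))
      expect_lte(min(abs(d)), m@margin + 1e-6)
  }
})

test_that("reports conserve counts and expose accuracies", {
  set.seed(3)
  f <- rbind(makeFeatures(30, 0.9, 3, 0.02, 0.5, "SOUND"),
             makeFeatures(30, 0.4, 18, 0.02, 0.5, "CRACKED"))
  sp <- splitFeatures(f, seed = 2L)
  m <- fitLDA(sp$calibration)
  rep <- evaluateModel(m, sp$calibration, sp$validation)
  expect_equal(totalAccuracy(rep, "validation"), 100)
  expect_equal(totalAccuracy(rep, "calibration"), 100)
  tb <- rep@table
  expect_true(all(tb$correct + tb$incorrect == tb$n))

  # a constant classifier on balanced data scores 50%
  const <- new("LinearClassifier", weights = c(R = 1e-12, D = 0),
               bias = 1, kind = "LDA", featureNames = c("R", "D"),
               positiveClass = "CRACKED", negativeClass = "SOUND",
               center = numeric(0), scale = numeric(0),
               supportIndex = integer(0), margin = NA_real_)
  repc <- evaluateModel(const, sp$calibration, sp$validation)
  expect_equal(totalAccuracy(repc, "validation"), 50)

  path <- file.path(withr::local_tempdir(), "report.tsv")
  writeReport(rep, path)
  back <- utils::read.delim(path)
  expect_equal(sum(back$n), nrow(f))
})

test_that("degenerate classifier inputs are rejected", {
  f <- makeFeatures(10, 0.8, 5, label = "SOUND")
  expect_error(fitLDA(f), "two classes")
  f2 <- rbind(f, makeFeatures(1, 0.5, 10, label = "CRACKED"))
  expect_error(fitSVM(f2), "degenerate")
  expect_error(fitSVM(rbind(f, makeFeatures(5, 0.5, 10, label = "CRACKED")),
                      cost = -1), "cost")
})
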