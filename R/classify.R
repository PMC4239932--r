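#' Stratified calibration/validation split of a feature table
#'
#' Splits each class separately with a seeded draw: the calibration part
#' gets `floor(fraction * class size)` samples (75% of 112 = 84, leaving
#' 28 for validation), the rest go to validation; the partition is
#' disjoint and exhaustive.
#'
#' @param features data.frame with a `label` column (SOUND/CRACKED).
#' @param fraction calibration fraction (default 0.75).
#' @param seed integer seed.
#' @return list with elements `calibration` and `validation`.
#' @export
splitFeatures <- function(features, fraction = 0.75, seed = 1L) {
  labs <- unique(features$label)
  if (length(labs) < 2L) stop("both classes must be present to split")
  calIdx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(labs, function(cl) {
      rows <- which(features$label == cl)
      if (length(rows) < 2L)
        stop("class ", cl, " has fewer than 2 samples")
      nCal <- floor(fraction * length(rows))
      if (nCal < 1L || nCal >= length(rows))
        stop("split leaves an empty calibration or validation set for ", cl)
      sample(rows, nCal)
    }))
  })
  list(calibration = features[sort(calIdx), , drop = FALSE],
       validation  = features[-sort(calIdx), , drop = FALSE])
}

.featureMatrix <- function(features, featureNames) {
  missing <- setdiff(featureNames, names(features))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  as.matrix(features[, featureNames, drop = FALSE])
}

#' Fit Fisher linear discriminant on shape features
#'
#' Weight vector proportional to Sw^-1 (mu_pos - mu_neg) with Sw the
#' pooled within-class scatter; the bias places the boundary at the
#' midpoint of the projected class means (equal priors — the benchmark
#' design is balanced). A singular scatter is ridge-regularized by
#' 1e-8 * trace.
#'
#' @param calibration feature data.frame with a `label` column.
#' @param featureNames feature columns to use (default `c("R", "D")`;
#'   pass a single name for a univariate discriminant).
#' @param positive label treated as the positive class
#'   (default `"CRACKED"`).
#' @return A [LinearClassifier-class] of kind `"LDA"`.
#' @export
fitLDA <- function(calibration, featureNames = c("R", "D"),
                   positive = "CRACKED") {
  X <- .featureMatrix(calibration, featureNames)
  lab <- calibration$label
  classes <- unique(lab)
  if (length(classes) != 2L) stop("LDA needs exactly two classes")
  negative <- setdiff(classes, positive)
  if (!positive %in% classes) stop("positive class absent from data")
  Xp <- X[lab == positive, , drop = FALSE]
  Xn <- X[lab == negative, , drop = FALSE]
  muP <- colMeans(Xp); muN <- colMeans(Xn)
  Sw <- crossprod(sweep(Xp, 2L, muP)) + crossprod(sweep(Xn, 2L, muN))
  w <- tryCatch(solve(Sw, muP - muN), error = function(e) {
    reg <- Sw + diag(1e-8 * sum(diag(Sw)), nrow(Sw))
    tryCatch(solve(reg, muP - muN),
             error = function(e2) stop(
               "within-class scatter singular even after regularization"))
  })
  w <- as.numeric(w); names(w) <- featureNames
  bias <- -sum(w * (muP + muN) / 2)
  new("LinearClassifier", weights = w, bias = bias, kind = "LDA",
      featureNames = featureNames, positiveClass = positive,
      negativeClass = negative, center = numeric(0), scale = numeric(0),
      supportIndex = integer(0), margin = NA_real_)
}

#' Fit a linear soft-margin SVM on shape features
#'
#' Maximum-margin linear separator (libsvm via e1071) with penalty `C`.
#' Features are z-scored with calibration statistics by default; LDA is
#' affine-invariant but the SVM penalty is not, so standardization keeps
#' `C` comparable across feature scales.
#'
#' @param calibration feature data.frame with a `label` column.
#' @param cost soft-margin penalty C > 0 (default 1).
#' @param featureNames feature columns to use.
#' @param positive label treated as the positive class.
#' @param standardize z-score features with calibration statistics
#'   (default TRUE).
#' @return A [LinearClassifier-class] of kind `"SVM"`; `margin` is the
#'   geometric margin 1/||w|| in (standardized) feature units and
#'   `supportIndex` indexes the support vectors within `calibration`.
#' @export
fitSVM <- function(calibration, cost = 1, featureNames = c("R", "D"),
                   positive = "CRACKED", standardize = TRUE) {
  if (cost <= 0) stop("cost must be > 0")
  X <- .featureMatrix(calibration, featureNames)
  lab <- calibration$label
  classes <- unique(lab)
  if (length(classes) != 2L) stop("SVM needs exactly two classes")
  negative <- setdiff(classes, positive)
  if (min(table(lab)) < 2L)
    stop("degenerate class with a single sample")
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0] <- 1
    Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  } else {
    ctr <- numeric(0); scl <- numeric(0); Z <- X
  }
  y <- factor(ifelse(lab == positive, positive, negative),
              levels = c(positive, negative))
  ## tight solver tolerance: the default 1e-3 termination leaves the
  ## separator visibly short of the true maximum-margin solution
  m <- e1071::svm(Z, y, kernel = "linear", cost = cost, scale = FALSE,
                  tolerance = 1e-7)
  w <- as.numeric(crossprod(m$coefs, m$SV))
  bias <- -m$rho
  ## libsvm orients the decision value toward its internal first label;
  ## align so that w.z + b > 0 predicts the positive class
  pred <- as.character(predict(m, Z))
  d <- Z %*% w + bias
  if (mean((d > 0) == (pred == positive)) < 0.5) {
    w <- -w; bias <- -bias
  }
  names(w) <- featureNames
  new("LinearClassifier", weights = w, bias = bias, kind = "SVM",
      featureNames = featureNames, positiveClass = positive,
      negativeClass = negative, center = ctr, scale = scl,
      supportIndex = as.integer(m$index),
      margin = 1 / sqrt(sum(w^2)))
}

#' Decision values and class predictions of a linear classifier
#'
#' @param model a [LinearClassifier-class].
#' @param features feature data.frame (or matrix with named columns).
#' @return `decisionValues`: numeric w.x + b per row; `predictClass`:
#'   character vector of predicted labels.
#' @export
decisionValues <- function(model, features) {
  stopifnot(is(model, "LinearClassifier"))
  X <- .featureMatrix(as.data.frame(features), model@featureNames)
  if (length(model@center))
    X <- sweep(sweep(X, 2L, model@center), 2L, model@scale, "/")
  as.numeric(X %*% model@weights + model@bias)
}

#' @rdname decisionValues
#' @export
predictClass <- function(model, features) {
  ifelse(decisionValues(model, features) > 0,
         model@positiveClass, model@negativeClass)
}

#' Per-class accuracy report for calibration and validation sets
#'
#' @param model a fitted [LinearClassifier-class].
#' @param calibration,validation feature data.frames with `label` columns.
#' @return A [ClassificationReport-class] with per-class correct /
#'   incorrect counts and accuracies plus the total accuracy per set.
#' @export
evaluateModel <- function(model, calibration, validation) {
  stopifnot(is(model, "LinearClassifier"))
  oneSet <- function(features, setName) {
    pred <- predictClass(model, features)
    do.call(rbind, lapply(unique(features$label), function(cl) {
      rows <- features$label == cl
      ok <- sum(pred[rows] == cl)
      data.frame(set = setName, class = cl, n = sum(rows), correct = ok,
                 incorrect = sum(rows) - ok,
                 accuracy = 100 * ok / sum(rows))
    }))
  }
  tab <- rbind(oneSet(calibration, "calibration"),
               oneSet(validation, "validation"))
  total <- vapply(c("calibration", "validation"), function(s) {
    sub <- tab[tab$set == s, ]
    100 * sum(sub$correct) / sum(sub$n)
  }, numeric(1))
  new("ClassificationReport", table = tab, total = total,
      kind = model@kind)
}

#' Total accuracy of a report
#'
#' @param report a [ClassificationReport-class].
#' @param set `"validation"` (default) or `"calibration"`.
#' @return Total accuracy in percent.
#' @export
totalAccuracy <- function(report, set = c("validation", "calibration")) {
  set <- match.arg(set)
  unname(report@total[set])
}

#' Write a classification report as delimited text
#'
#' @param report a [ClassificationReport-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  tab <- report@table
  tab$kind <- report@kind
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
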