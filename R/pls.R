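## NIPALS partial least squares (PLS1) and pixel-wise PLS-DA scoring.
##
## The discriminant is an ordinary PLS regression of mean-centered spectra
## on a 0/1 class code: X = T P' + E, Y = U C' + F, with the inner relation
## U = T B + G estimated by least squares. Mean-centering only, no
## autoscaling: reflectance bands share units.

.nipals <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y length must match nrow(X)")
  if (k < 1L || k > min(n - 1L, p))
    stop(sprintf("component count k = %d out of range [1, %d]",
                 k, min(n - 1L, p)))
  xMean <- colMeans(X)
  yMean <- mean(y)
  E <- sweep(X, 2L, xMean)
  if (max(abs(E)) == 0) stop("zero-variance X: nothing to decompose")
  f <- y - yMean
  Tm <- matrix(0, n, k); P <- matrix(0, p, k); W <- matrix(0, p, k)
  U <- matrix(0, n, k); C <- matrix(0, 1, k)
  achieved <- 0L
  for (a in seq_len(k)) {
    w <- crossprod(E, f)                      # p x 1
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * (1 + sqrt(sum(f^2)))) break   # y residual exhausted
    w <- w / nw
    tt <- E %*% w
    t2 <- sum(tt^2)
    if (t2 < 1e-24) break
    pp <- crossprod(E, tt) / t2
    cc <- sum(f * tt) / t2
    U[, a] <- f                               # y-block score entering comp a
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pp; C[1, a] <- cc
    E <- E - tcrossprod(tt, pp)
    f <- f - tt * cc
    achieved <- a
  }
  if (achieved == 0L) stop("no PLS component could be extracted")
  idx <- seq_len(achieved)
  Tm <- Tm[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  W <- W[, idx, drop = FALSE]; U <- U[, idx, drop = FALSE]
  C <- C[, idx, drop = FALSE]
  B <- solve(crossprod(Tm), crossprod(Tm, U))  # inner relation (T'T)^-1 T'U
  G <- U - Tm %*% B
  list(T = Tm, P = P, W = W, U = U, C = C, B = B, G = G,
       E = E, f = f, xMean = xMean, yMean = yMean, k = achieved)
}

.betaForK <- function(np, k) {
  idx <- seq_len(k)
  W <- np$W[, idx, drop = FALSE]
  P <- np$P[, idx, drop = FALSE]
  C <- np$C[, idx, drop = FALSE]
  as.numeric(W %*% solve(crossprod(P, W), t(C)))
}

#' Fit a NIPALS PLS model of spectra on a 0/1 response
#'
#' @param X spectra matrix (samples x bands); mean-centered internally.
#' @param y numeric 0/1 response (class code).
#' @param k number of latent variables, `1 <= k <= min(n - 1, bands)`.
#' @return A [PLSFit-class]. Fewer than `k` components are returned (with a
#'   warning) if the response is exhausted early.
#' @export
fitPLS <- function(X, y, k) {
  np <- .nipals(X, y, as.integer(k))
  if (np$k < k)
    warning(sprintf("response exhausted after %d of %d components", np$k, k))
  new("PLSFit", scoresX = np$T, loadingsX = np$P, residualX = np$E,
      scoresY = np$U, loadingsY = np$C,
      residualY = matrix(np$f, ncol = 1L),
      innerCoef = np$B, innerResidual = np$G, weights = np$W,
      xMean = np$xMean, yMean = np$yMean, beta = .betaForK(np, np$k))
}

#' @describeIn fitPLS regression coefficients mapping centered X to
#'   centered y.
#' @param fit a [PLSFit-class].
#' @export
plsBeta <- function(fit) fit@beta

#' Select the latent-variable count by validation RMSE
#'
#' Splits the spectra into a seeded random calibration/validation partition
#' (70/30 by default), fits NIPALS models with 1..`maxK` components on the
#' calibration part, and evaluates
#' \deqn{RMSEV(k) = \sqrt{\sum_i (y_{v,i} - y_{ref,i})^2 / n}}
#' on the held-out part. The chosen count minimizes the curve; ties go to
#' the smaller k.
#'
#' @param X spectra matrix.
#' @param y numeric 0/1 response.
#' @param maxK largest component count to consider (default 20; capped at
#'   what the calibration split supports).
#' @param splitSeed integer seed for the random split.
#' @param fraction calibration fraction of the split.
#' @return An [RMSEVCurve-class].
#' @export
selectComponents <- function(X, y, maxK = 20L, splitSeed = 1L,
                             fraction = 0.7) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (maxK < 1L) stop("maxK must be >= 1")
  nCal <- floor(fraction * n)
  if (nCal < 2L || nCal >= n)
    stop("validation split empty or calibration too small")
  cal <- withr::with_seed(as.integer(splitSeed), sample.int(n, nCal))
  val <- setdiff(seq_len(n), cal)
  kMax <- min(as.integer(maxK), nCal - 1L, ncol(X))
  np <- .nipals(X[cal, , drop = FALSE], y[cal], kMax)
  Xv <- sweep(X[val, , drop = FALSE], 2L, np$xMean)
  rmsev <- vapply(seq_len(np$k), function(k) {
    pred <- Xv %*% .betaForK(np, k) + np$yMean
    sqrt(sum((pred - y[val])^2) / length(val))
  }, numeric(1))
  new("RMSEVCurve", values = rmsev, chosen = which.min(rmsev))
}

#' Train a PLS-DA model from labeled region spectra
#'
#' Maps the positive region(s) to y = 1 and the negative region(s) to
#' y = 0, picks the latent-variable count by [selectComponents], and refits
#' on all selected spectra. Two variants are standard: crack-vs-sound and
#' crack-vs-specular; the latter is the pipeline default because it
#' suppresses specular highlights that otherwise survive as false
#' positives.
#'
#' @param ls a [LabeledSpectra-class] (e.g. from [sampleSpectra]).
#' @param positive region label(s) coded 1 (default `"CRACK"`).
#' @param negative region label(s) coded 0 (default `"SPECULAR"`).
#' @param maxK largest latent-variable count considered.
#' @param splitSeed seed for the internal RMSEV split.
#' @return A [PLSDAModel-class].
#' @export
trainPLSDA <- function(ls, positive = "CRACK", negative = "SPECULAR",
                       maxK = 20L, splitSeed = 1L) {
  stopifnot(is(ls, "LabeledSpectra"))
  lab <- as.character(ls@label)
  use <- lab %in% c(positive, negative)
  if (!any(lab %in% positive) || !any(lab %in% negative))
    stop("training spectra must contain both positive and negative regions")
  X <- ls@spectra[use, , drop = FALSE]
  y <- as.numeric(lab[use] %in% positive)
  curve <- selectComponents(X, y, maxK = maxK, splitSeed = splitSeed)
  np <- .nipals(X, y, curve@chosen)
  new("PLSDAModel", beta = .betaForK(np, np$k), ncomp = np$k,
      wavelength = ls@wavelength, xMean = np$xMean, yMean = np$yMean,
      positiveLabel = positive, negativeLabel = negative, rmsev = curve)
}

#' Project a cube to a per-pixel PLS-DA score image
#'
#' Per-pixel score = (spectrum - xMean) . beta + yMean; values are
#' continuous and nominally near [0, 1], with the positive class near 1.
#'
#' @param model a [PLSDAModel-class].
#' @param cube reflectance [HyperCube-class] on the model's wavelength
#'   grid.
#' @return Numeric score matrix (rows x cols).
#' @export
scoreImage <- function(model, cube) {
  stopifnot(is(model, "PLSDAModel"), is(cube, "HyperCube"))
  if (!isTRUE(all.equal(model@wavelength, cube@wavelength)))
    stop("cube wavelength grid does not match the model grid")
  d <- dim(cube@data)
  X <- cube@data
  dim(X) <- c(d[1] * d[2], d[3])
  s <- X %*% model@beta + (model@yMean - sum(model@xMean * model@beta))
  matrix(s, d[1], d[2])
}

#' Binarize a score image
#'
#' Foreground where score >= threshold (inclusive).
#'
#' @param scores numeric score matrix.
#' @param threshold score cut (default 0.5).
#' @return Logical matrix.
#' @export
binarizeScores <- function(scores, threshold = 0.5) {
  scores >= threshold
}

#' Dominant beta-coefficient extrema
#'
#' Diagnostic reporting the wavelengths of the largest-magnitude local
#' extrema of the model's beta coefficients (the bands the discriminant
#' leans on hardest).
#'
#' @param model a [PLSDAModel-class].
#' @param n number of extrema to report.
#' @return data.frame with columns band, wavelength, beta, ordered by
#'   |beta| descending.
#' @export
betaPeaks <- function(model, n = 3L) {
  b <- model@beta
  p <- length(b)
  d <- diff(b)
  isExt <- c(TRUE, d[-1] * d[-length(d)] < 0, TRUE)  # interior sign changes
  cand <- which(isExt)
  cand <- cand[order(abs(b[cand]), decreasing = TRUE)]
  cand <- cand[seq_len(min(n, length(cand)))]
  data.frame(band = cand, wavelength = model@wavelength[cand],
             beta = b[cand])
}

#' Serialize / restore a PLS-DA model as delimited text
#'
#' Key=value header (component count, class mapping, yMean, RMSEV curve)
#' followed by a per-band table of wavelength, beta and xMean.
#'
#' @param model a [PLSDAModel-class].
#' @param path file path.
#' @return `path` invisibly; `readPLSDAModel` returns the model.
#' @export
writePLSDAModel <- function(model, path) {
  stopifnot(is(model, "PLSDAModel"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncomp=%d", model@ncomp),
    sprintf("positive=%s", paste(model@positiveLabel, collapse = ",")),
    sprintf("negative=%s", paste(model@negativeLabel, collapse = ",")),
    sprintf("yMean=%.17g", model@yMean),
    sprintf("rmsev=%s", paste(sprintf("%.17g", model@rmsev@values),
                              collapse = ",")),
    sprintf("rmsevChosen=%d", model@rmsev@chosen),
    "wavelength\tbeta\txMean"), con)
  utils::write.table(
    data.frame(model@wavelength, model@beta, model@xMean),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePLSDAModel
#' @export
readPLSDAModel <- function(path) {
  lines <- readLines(path)
  hdrEnd <- which(lines == "wavelength\tbeta\txMean")
  kv <- strsplit(lines[seq_len(hdrEnd - 1L)], "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  tab <- utils::read.delim(text = lines[-seq_len(hdrEnd)], header = FALSE)
  rv <- as.numeric(strsplit(vals[keys == "rmsev"], ",")[[1L]])
  new("PLSDAModel",
      beta = tab[[2L]], ncomp = as.integer(vals[keys == "ncomp"]),
      wavelength = tab[[1L]], xMean = tab[[3L]],
      yMean = as.numeric(vals[keys == "yMean"]),
      positiveLabel = strsplit(vals[keys == "positive"], ",")[[1L]],
      negativeLabel = strsplit(vals[keys == "negative"], ",")[[1L]],
      rmsev = new("RMSEVCurve", values = rv,
                  chosen = as.integer(vals[keys == "rmsevChosen"])))
}
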