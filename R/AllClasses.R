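#' @import methods
NULL

#' Region labels used throughout the package
#'
#' The four tissue classes annotated on tomato scenes, in the fixed order
#' used by ROI rasters (pixel codes 1-4; 0 = unlabeled background).
#'
#' @export
REGION_LEVELS <- c("SOUND", "CRACK", "STEM", "SPECULAR")

#' HyperCube: a hyperspectral image cube
#'
#' A 3-D raster (rows x cols x bands) together with its band-center
#' wavelength grid in nanometres. `kind` records whether the cube holds raw
#' detector counts or calibrated relative reflectance.
#'
#' @slot data numeric 3-D array, rows x cols x bands.
#' @slot wavelength numeric vector of band centers (nm), strictly increasing.
#' @slot kind either `"counts"` or `"reflectance"`.
#'
#' @export
setClass("HyperCube",
  representation(data = "array", wavelength = "numeric", kind = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L)
      return("data must be a 3-D array (rows x cols x bands)")
    if (d[3L] != length(object@wavelength))
      return(sprintf("band count (%d) != wavelength count (%d)",
                     d[3L], length(object@wavelength)))
    if (length(object@wavelength) && any(diff(object@wavelength) <= 0))
      return("wavelengths must be strictly increasing")
    if (!object@kind %in% c("counts", "reflectance"))
      return("kind must be 'counts' or 'reflectance'")
    rng <- suppressWarnings(range(object@data))  # single pass, no copy
    if (anyNA(rng) || !all(is.finite(rng)))
      return("cube values must be finite")
    if (object@kind == "counts" && rng[1L] < 0)
      return("raw counts must be non-negative")
    TRUE
  })

#' Construct a HyperCube
#'
#' @param data numeric 3-D array (rows x cols x bands).
#' @param wavelength numeric vector of band-center wavelengths (nm).
#' @param kind `"counts"` (raw detector values) or `"reflectance"`.
#' @return A [HyperCube-class] object.
#' @examples
#' cube <- HyperCube(array(0.5, c(4, 4, 3)), c(1000, 1100, 1200))
#' dim(cube)
#' @export
HyperCube <- function(data, wavelength, kind = c("reflectance", "counts")) {
  kind <- match.arg(kind)
  new("HyperCube", data = data, wavelength = as.numeric(wavelength),
      kind = kind)
}

#' LabeledSpectra: region-of-interest spectra with tissue labels
#'
#' @slot spectra numeric matrix, one spectrum per row (n x bands).
#' @slot label factor with levels from [REGION_LEVELS], one per row.
#' @slot wavelength numeric band-center wavelengths (nm).
#'
#' @export
setClass("LabeledSpectra",
  representation(spectra = "matrix", label = "factor", wavelength = "numeric"),
  validity = function(object) {
    if (nrow(object@spectra) != length(object@label))
      return("one label required per spectrum row")
    if (ncol(object@spectra) != length(object@wavelength))
      return("spectra band count != wavelength count")
    if (!all(levels(object@label) %in% REGION_LEVELS))
      return("labels outside the SOUND/CRACK/STEM/SPECULAR set")
    TRUE
  })

#' Construct a LabeledSpectra object
#'
#' @param spectra numeric matrix (n spectra x bands).
#' @param label character or factor of region labels, one per row.
#' @param wavelength numeric band-center wavelengths (nm).
#' @return A [LabeledSpectra-class] object.
#' @export
LabeledSpectra <- function(spectra, label, wavelength) {
  if (!all(as.character(label) %in% REGION_LEVELS))
    stop("labels outside the SOUND/CRACK/STEM/SPECULAR set")
  new("LabeledSpectra", spectra = as.matrix(spectra),
      label = factor(as.character(label), levels = REGION_LEVELS),
      wavelength = as.numeric(wavelength))
}

#' PLSFit: NIPALS partial least squares decomposition
#'
#' Factor matrices of the bilinear model X = T P' + E, Y = U C' + F with the
#' inner relation U = T B + G estimated by least squares, plus the centering
#' vectors removed before decomposition.
#'
#' @slot scoresX,loadingsX,residualX X-block scores (T), loadings (P),
#'   residual (E).
#' @slot scoresY,loadingsY,residualY Y-block scores (U), loadings (C),
#'   residual (F).
#' @slot innerCoef,innerResidual inner-relation coefficients B
#'   (= (T'T)^-1 T'U) and residual G.
#' @slot weights X-block weight vectors W (columns, one per component).
#' @slot xMean,yMean centering vectors.
#' @slot beta regression coefficients mapping centered X to centered y.
#'
#' @export
setClass("PLSFit",
  representation(scoresX = "matrix", loadingsX = "matrix", residualX = "matrix",
                 scoresY = "matrix", loadingsY = "matrix", residualY = "matrix",
                 innerCoef = "matrix", innerResidual = "matrix",
                 weights = "matrix", xMean = "numeric", yMean = "numeric",
                 beta = "numeric"))

#' RMSEVCurve: validation error per latent-variable count
#'
#' @slot values root mean square error of validation for k = 1..maxK.
#' @slot chosen the selected component count (argmin, ties to smaller k).
#'
#' @export
setClass("RMSEVCurve",
  representation(values = "numeric", chosen = "integer"),
  validity = function(object) {
    if (any(object@values < 0)) return("RMSEV values must be >= 0")
    if (length(object@values)) {
      if (object@chosen < 1L || object@chosen > length(object@values))
        return("chosen component count out of range")
      if (abs(object@values[object@chosen] - min(object@values)) > 1e-12)
        return("chosen count must minimize the curve")
    }
    TRUE
  })

#' PLSDAModel: a fitted PLS discriminant model for cube scoring
#'
#' Stores the band-wise beta coefficients of a PLS regression of spectra on
#' a 0/1 class code, the centering statistics needed to score new pixels,
#' and the class mapping (positive label scores toward 1).
#'
#' @slot beta numeric regression coefficients, one per band.
#' @slot ncomp integer latent-variable count (selected by RMSEV).
#' @slot wavelength numeric band grid (nm).
#' @slot xMean,yMean centering statistics from training.
#' @slot positiveLabel,negativeLabel region labels mapped to y = 1 / y = 0.
#' @slot rmsev the [RMSEVCurve-class] used to pick `ncomp`.
#'
#' @export
setClass("PLSDAModel",
  representation(beta = "numeric", ncomp = "integer", wavelength = "numeric",
                 xMean = "numeric", yMean = "numeric",
                 positiveLabel = "character", negativeLabel = "character",
                 rmsev = "RMSEVCurve"),
  validity = function(object) {
    if (length(object@beta) != length(object@wavelength))
      return("beta length != band count")
    if (length(object@xMean) != length(object@beta))
      return("xMean length != band count")
    if (object@ncomp < 1L)
      return("ncomp must be >= 1")
    TRUE
  })

#' RegionImage: a labeled binary region raster
#'
#' A binary mask plus its 8-connected component labeling and per-component
#' pixel counts, the working object of the morphological cleanup stage.
#'
#' @slot mask logical matrix (foreground = TRUE).
#' @slot labels integer matrix; 0 = background, components numbered 1..n.
#' @slot sizes integer vector of component pixel counts (index = label).
#'
#' @export
setClass("RegionImage",
  representation(mask = "matrix", labels = "matrix", sizes = "integer"),
  validity = function(object) {
    if (!identical(dim(object@mask), dim(object@labels)))
      return("mask and labels must have identical shape")
    n <- length(object@sizes)
    if (n && !identical(sort(unique(as.integer(object@labels[object@labels > 0]))),
                        seq_len(n)))
      return("labels must be exactly 1..n_components")
    if (sum(object@sizes) != sum(object@mask))
      return("component sizes must sum to foreground pixel count")
    TRUE
  })

#' LinearClassifier: a fitted linear decision rule on shape features
#'
#' Fisher LDA or linear soft-margin SVM on the (R, D) feature plane. The
#' decision value is w.x + b on (optionally standardized) features; positive
#' values predict `positiveClass`.
#'
#' @slot weights named numeric weight vector over features.
#' @slot bias numeric intercept.
#' @slot kind `"LDA"` or `"SVM"`.
#' @slot featureNames features the model was trained on.
#' @slot positiveClass,negativeClass class labels on either side of the
#'   boundary.
#' @slot center,scale standardization statistics (zero-length if unused).
#' @slot supportIndex integer indices of support vectors within the
#'   calibration set (SVM only).
#' @slot margin geometric margin 1/||w|| in standardized feature units
#'   (SVM only, NA for LDA).
#'
#' @export
setClass("LinearClassifier",
  representation(weights = "numeric", bias = "numeric", kind = "character",
                 featureNames = "character", positiveClass = "character",
                 negativeClass = "character", center = "numeric",
                 scale = "numeric", supportIndex = "integer",
                 margin = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("LDA", "SVM")) return("kind must be LDA or SVM")
    if (length(object@weights) != length(object@featureNames))
      return("one weight per feature required")
    if (all(object@weights == 0)) return("weight vector must be non-zero")
    TRUE
  })

#' ClassificationReport: per-class accuracy table
#'
#' Counts and accuracies for calibration and validation sets in the layout
#' of a two-class confusion summary (correct / incorrect / accuracy per
#' class plus total accuracy per set).
#'
#' @slot table data.frame with columns set, class, n, correct, incorrect,
#'   accuracy.
#' @slot total named numeric, total accuracy (%) per set.
#' @slot kind classifier kind the report describes.
#'
#' @export
setClass("ClassificationReport",
  representation(table = "data.frame", total = "numeric", kind = "character"),
  validity = function(object) {
    tb <- object@table
    if (!all(c("set", "class", "n", "correct", "incorrect", "accuracy")
             %in% names(tb)))
      return("report table missing required columns")
    if (any(tb$correct + tb$incorrect != tb$n))
      return("correct + incorrect must equal class size")
    if (any(tb$accuracy < 0 | tb$accuracy > 100))
      return("accuracies must lie in [0, 100]%")
    TRUE
  })

#' EndmemberSet: region endmember spectra for phantom rendering
#'
#' @slot spectra numeric matrix, 4 rows named SOUND/CRACK/STEM/SPECULAR.
#' @slot background numeric background spectrum (dark stage surface).
#' @slot wavelength numeric band grid (nm).
#' @slot textureSd sd of the per-pixel multiplicative lognormal texture.
#' @slot noiseSd sd of the per-voxel additive sensor noise (relative).
#'
#' @export
setClass("EndmemberSet",
  representation(spectra = "matrix", background = "numeric",
                 wavelength = "numeric", textureSd = "numeric",
                 noiseSd = "numeric"),
  validity = function(object) {
    if (!identical(rownames(object@spectra), REGION_LEVELS))
      return("endmember rows must be SOUND, CRACK, STEM, SPECULAR")
    if (ncol(object@spectra) != length(object@wavelength))
      return("endmember band count != wavelength count")
    if (any(object@spectra < 0)) return("endmember reflectance must be >= 0")
    sp <- object@spectra
    if (!all(sp["SPECULAR", ] > sp["SOUND", ]) ||
        !all(sp["SPECULAR", ] > sp["CRACK", ]) ||
        !all(sp["SPECULAR", ] > sp["STEM", ]))
      return("specular endmember must exceed all others at every band")
    TRUE
  })

#' PhantomScene: one synthetic tomato scene with ground truth
#'
#' @slot cube reflectance [HyperCube-class].
#' @slot truth integer matrix of region codes (0 = background, 1 = sound,
#'   2 = crack, 3 = stem scar, 4 = specular).
#' @slot label scene class, `"SOUND"` or `"CRACKED"`.
#' @slot config the [phantomConfig] list that produced the scene.
#' @slot seed integer seed the scene was rendered with.
#'
#' @export
setClass("PhantomScene",
  representation(cube = "HyperCube", truth = "matrix", label = "character",
                 config = "list", seed = "integer"),
  validity = function(object) {
    if (!identical(dim(object@truth), dim(object@cube@data)[1:2]))
      return("truth raster shape must match cube spatial shape")
    if (!object@label %in% c("SOUND", "CRACKED"))
      return("scene label must be SOUND or CRACKED")
    ncrack <- sum(object@truth == 2L)
    if (object@label == "CRACKED" && ncrack < 1L)
      return("cracked scenes must contain at least one crack pixel")
    if (object@label == "SOUND" && ncrack > 0L)
      return("sound scenes must contain no crack pixels")
    TRUE
  })

#' PhantomBenchmark: a lazy manifest of phantom scenes
#'
#' Scene cubes at full size are ~150 MB each, so a benchmark of 224 scenes
#' is never materialized as a whole; this object records the per-scene seeds
#' and labels plus the shared configuration, and scenes are rendered on
#' demand with [benchmarkScene].
#'
#' @slot manifest data.frame with columns scene_id, label, seed.
#' @slot config shared [phantomConfig] list (label/seed filled per scene).
#' @slot seed master seed the per-scene seeds were drawn from.
#'
#' @export
setClass("PhantomBenchmark",
  representation(manifest = "data.frame", config = "list", seed = "integer"),
  validity = function(object) {
    m <- object@manifest
    if (!all(c("scene_id", "label", "seed") %in% names(m)))
      return("manifest must have scene_id, label, seed columns")
    if (anyDuplicated(m$seed)) return("scene seeds must be distinct")
    TRUE
  })
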