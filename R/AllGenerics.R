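#' Accessor generics
#'
#' Small accessor family for the package's S4 classes: `wavelengths` returns
#' the band grid in nm, `cubeData` the raw 3-D array, `spectra` the spectra
#' matrix, `regionLabels` the per-row region labels, `regionMask` the binary
#' mask, `componentSizes` the per-component pixel counts, `sceneTruth` the
#' ground-truth raster and `sceneLabel` the scene class.
#'
#' @param object an object of the matching crackscan class.
#' @return The slot value described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("cubeData", function(object) standardGeneric("cubeData"))

#' @rdname accessors
#' @export
setGeneric("spectra", function(object) standardGeneric("spectra"))

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("regionMask", function(object) standardGeneric("regionMask"))

#' @rdname accessors
#' @export
setGeneric("componentSizes", function(object) standardGeneric("componentSizes"))

#' @rdname accessors
#' @export
setGeneric("sceneTruth", function(object) standardGeneric("sceneTruth"))

#' @rdname accessors
#' @export
setGeneric("sceneLabel", function(object) standardGeneric("sceneLabel"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "HyperCube", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("wavelengths", "LabeledSpectra", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("wavelengths", "PLSDAModel", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("wavelengths", "EndmemberSet", function(object) object@wavelength)

#' @rdname accessors
#' @export
setMethod("cubeData", "HyperCube", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("spectra", "LabeledSpectra", function(object) object@spectra)

#' @rdname accessors
#' @export
setMethod("spectra", "EndmemberSet", function(object) object@spectra)

#' @rdname accessors
#' @export
setMethod("regionLabels", "LabeledSpectra", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("regionMask", "RegionImage", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("componentSizes", "RegionImage", function(object) object@sizes)

#' @rdname accessors
#' @export
setMethod("sceneTruth", "PhantomScene", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("sceneLabel", "PhantomScene", function(object) object@label)

#' @describeIn HyperCube spatial and spectral dimensions
#' @param x a HyperCube
#' @export
setMethod("dim", "HyperCube", function(x) dim(x@data))

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube [%s]: %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              object@kind, d[1], d[2], d[3],
              min(object@wavelength), max(object@wavelength)))
})

setMethod("show", "LabeledSpectra", function(object) {
  cat(sprintf("LabeledSpectra: %d spectra x %d bands\n",
              nrow(object@spectra), ncol(object@spectra)))
  print(table(object@label))
})

setMethod("show", "PLSDAModel", function(object) {
  cat(sprintf("PLSDAModel: %s (y=1) vs %s (y=0), %d latent variables, %d bands\n",
              paste(object@positiveLabel, collapse = "+"),
              paste(object@negativeLabel, collapse = "+"),
              object@ncomp, length(object@beta)))
  cat(sprintf("  RMSEV at chosen k: %.4f\n",
              object@rmsev@values[object@rmsev@chosen]))
})

setMethod("show", "RegionImage", function(object) {
  cat(sprintf("RegionImage: %d x %d, %d foreground px in %d component(s)\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              length(object@sizes)))
})

setMethod("show", "LinearClassifier", function(object) {
  cat(sprintf("LinearClassifier [%s] on (%s): %s vs %s\n", object@kind,
              paste(object@featureNames, collapse = ", "),
              object@positiveClass, object@negativeClass))
  cat("  weights:", paste(sprintf("%s=%.4f", object@featureNames,
                                  object@weights), collapse = " "),
      sprintf(" bias=%.4f\n", object@bias))
  if (object@kind == "SVM")
    cat(sprintf("  %d support vectors, geometric margin %.4f\n",
                length(object@supportIndex), object@margin))
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport [%s]\n", object@kind))
  print(object@table, row.names = FALSE)
  for (s in names(object@total))
    cat(sprintf("  total %s accuracy: %.1f%%\n", s, object@total[[s]]))
})

setMethod("show", "PhantomScene", function(object) {
  d <- dim(object@cube@data)
  cat(sprintf("PhantomScene [%s], seed %d: %d x %d x %d\n", object@label,
              object@seed, d[1], d[2], d[3]))
  tab <- table(factor(object@truth, levels = 0:4,
                      labels = c("BACKGROUND", REGION_LEVELS)))
  print(tab)
})

setMethod("show", "PhantomBenchmark", function(object) {
  cat(sprintf("PhantomBenchmark: %d scenes (%d SOUND, %d CRACKED), master seed %d\n",
              nrow(object@manifest), sum(object@manifest$label == "SOUND"),
              sum(object@manifest$label == "CRACKED"), object@seed))
})
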