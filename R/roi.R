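#' Threshold the fruit body at the reflectance-maximum band
#'
#' Foreground = pixels whose reflectance at the band nearest `bandNm`
#' (default 1098 nm, where tomato tissue reflects most strongly) is at or
#' above `threshold`. This is the thresholding primitive used when
#' annotating ROIs and when restricting masks to the fruit interior.
#'
#' @param cube reflectance [HyperCube-class].
#' @param threshold reflectance cut, in [0.05, 1].
#' @param bandNm band to threshold at (nm).
#' @return Logical matrix, TRUE = fruit.
#' @export
fruitMask <- function(cube, threshold, bandNm = 1098) {
  stopifnot(is(cube, "HyperCube"))
  if (threshold < 0.05 || threshold > 1)
    stop("fruit threshold must lie in [0.05, 1]")
  b <- nearestBand(cube, bandNm)
  m <- cube@data[, , b] >= threshold
  if (!any(m)) warning("fruit mask is empty at threshold ", threshold)
  m
}

#' Extract labeled region-of-interest spectra from a cube
#'
#' One spectrum per labeled pixel of the ROI raster (codes 1 = sound,
#' 2 = crack, 3 = stem scar, 4 = specular; 0 = unlabeled, skipped).
#'
#' @param cube reflectance [HyperCube-class].
#' @param roi integer matrix of ROI codes, same spatial shape as `cube`.
#' @return A [LabeledSpectra-class].
#' @export
extractSpectra <- function(cube, roi) {
  stopifnot(is(cube, "HyperCube"))
  roi <- as.matrix(roi)
  d <- dim(cube@data)
  if (!identical(dim(roi), d[1:2]))
    stop("roi shape must match cube spatial shape")
  codes <- sort(unique(as.integer(roi)))
  if (any(!codes %in% 0:4))
    stop("roi contains labels outside 0..4 (SOUND/CRACK/STEM/SPECULAR)")
  idx <- which(roi > 0L)
  X <- cube@data
  dim(X) <- c(d[1] * d[2], d[3])
  LabeledSpectra(X[idx, , drop = FALSE],
                 REGION_LEVELS[roi[idx]],
                 cube@wavelength)
}

#' Randomly sample a fixed number of spectra per region
#'
#' Draws `perClass` spectra from each region present (training protocol:
#' 1000 per region). Sampling is without replacement; if a region pool is
#' smaller than requested the draw falls back to sampling with replacement
#' and warns. Reproducible for a fixed seed.
#'
#' @param ls a [LabeledSpectra-class].
#' @param perClass spectra to draw per region.
#' @param seed integer RNG seed.
#' @param classes regions to sample; default = all regions present.
#' @return A [LabeledSpectra-class] with `perClass` rows per region.
#' @export
sampleSpectra <- function(ls, perClass = 1000L, seed = 1L, classes = NULL) {
  stopifnot(is(ls, "LabeledSpectra"))
  present <- levels(droplevels(ls@label))
  if (is.null(classes)) classes <- present
  if (!all(classes %in% present))
    stop("requested class absent from spectra pool: ",
         paste(setdiff(classes, present), collapse = ", "))
  keep <- withr::with_seed(as.integer(seed), {
    unlist(lapply(classes, function(cl) {
      pool <- which(ls@label == cl)
      if (length(pool) < perClass) {
        warning(sprintf(
          "region %s has %d spectra < %d requested; sampling with replacement",
          cl, length(pool), perClass))
        sample(pool, perClass, replace = TRUE)
      } else {
        sample(pool, perClass)
      }
    }))
  })
  LabeledSpectra(ls@spectra[keep, , drop = FALSE],
                 as.character(ls@label[keep]), ls@wavelength)
}

#' Mean spectrum of one region
#'
#' @param ls a [LabeledSpectra-class].
#' @param label region name (one of SOUND, CRACK, STEM, SPECULAR).
#' @return Numeric vector, the arithmetic mean over that region's rows.
#' @export
meanSpectrum <- function(ls, label) {
  stopifnot(is(ls, "LabeledSpectra"))
  label <- match.arg(label, REGION_LEVELS)
  rows <- ls@label == label
  if (!any(rows)) stop("no spectra labeled ", label)
  colMeans(ls@spectra[rows, , drop = FALSE])
}

#' Write / read a spectra table as delimited text
#'
#' Tab-separated, wavelength header row, first column the region label.
#'
#' @param ls a [LabeledSpectra-class].
#' @param path output file.
#' @return `path` invisibly; `readSpectraTable` returns a
#'   [LabeledSpectra-class].
#' @export
writeSpectraTable <- function(ls, path) {
  stopifnot(is(ls, "LabeledSpectra"))
  df <- data.frame(label = as.character(ls@label), ls@spectra,
                   check.names = FALSE)
  names(df) <- c("label", format(ls@wavelength, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraTable
#' @export
readSpectraTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  LabeledSpectra(as.matrix(df[, -1, drop = FALSE]), df[[1L]],
                 as.numeric(names(df)[-1]))
}
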