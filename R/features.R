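## Stem-scar shape descriptors.
##
## Roundness R = 4*pi*Area / Circumference^2 (1 for a disk, lower for
## irregular shapes) and differential distance D = max - min distance from
## the region centroid to its boundary (0 for a disk, large when cracks
## extend radially). The boundary is the sub-pixel 0.5 iso-contour of the
## lightly smoothed mask: the raw staircase contour of a binary raster
## overestimates perimeter by ~7% and would bias R well below 1 for disks,
## while a 3x3 box smoothing keeps rasterized disks within a few percent
## of R = 1 yet preserves crack arms down to 2 px width.

.smooth3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  z <- matrix(0, n + 2L, p + 2L)
  z[2:(n + 1L), 2:(p + 1L)] <- m
  (z[1:n, 1:p] + z[1:n, 2:(p + 1L)] + z[1:n, 3:(p + 2L)] +
   z[2:(n + 1L), 1:p] + z[2:(n + 1L), 2:(p + 1L)] + z[2:(n + 1L), 3:(p + 2L)] +
   z[3:(n + 2L), 1:p] + z[3:(n + 2L), 2:(p + 1L)] + z[3:(n + 2L), 3:(p + 2L)]) / 9
}

## Sub-pixel boundary polygon(s) of a binary mask; coordinates in pixel
## units (pixel (i, j) sits at (i, j)). Returns the longest (outer)
## contour: list(x = rows, y = cols, length).
.maskContour <- function(mask) {
  m <- as.matrix(mask) * 1.0
  n <- nrow(m); p <- ncol(m)
  sm <- .smooth3(m)
  pad <- matrix(0, n + 2L, p + 2L)
  pad[2:(n + 1L), 2:(p + 1L)] <- sm
  cl <- grDevices::contourLines(0:(n + 1L), 0:(p + 1L), pad, levels = 0.5)
  if (!length(cl)) stop("mask has no 0.5 iso-contour")
  len <- vapply(cl, function(cc)
    sum(sqrt(diff(cc$x)^2 + diff(cc$y)^2)), numeric(1))
  main <- cl[[which.max(len)]]
  list(x = main$x, y = main$y, length = max(len))
}

#' Roundness from analytic area and circumference
#'
#' The bare shape equation R = 4 * pi * Area / Circumference^2; exposed so
#' analytic shapes (circle: R = 1; square: R = pi/4) can be evaluated
#' without rasterization.
#'
#' @param area region area.
#' @param circumference boundary length, same length unit.
#' @return Dimensionless roundness.
#' @examples
#' roundnessValue(pi * 10^2, 2 * pi * 10)  # 1
#' roundnessValue(4^2, 4 * 4)              # pi/4
#' @export
roundnessValue <- function(area, circumference) {
  4 * pi * area / circumference^2
}

.featureMask <- function(region, what) {
  if (is(region, "RegionImage")) {
    if (!sum(region@mask)) stop("empty region: cannot compute ", what)
    if (length(region@sizes) > 1L)
      warning(what, " computed on the union of ", length(region@sizes),
              " components")
    region@mask
  } else {
    m <- as.matrix(region)
    storage.mode(m) <- "logical"
    if (!sum(m)) stop("empty region: cannot compute ", what)
    m
  }
}

#' Roundness of a rasterized region
#'
#' Area is the foreground pixel count; circumference is the length of the
#' sub-pixel boundary contour polygon (see file notes on the estimator).
#'
#' @param region a [RegionImage-class] or logical mask (single component
#'   expected after cleanup; unions warn).
#' @return Dimensionless roundness, near 1 for a disk.
#' @export
roundness <- function(region) {
  m <- .featureMask(region, "roundness")
  roundnessValue(sum(m), .maskContour(m)$length)
}

#' Differential (min-max) boundary distance
#'
#' D = max - min of Euclidean distances from the region centroid (area
#' center of mass of the foreground pixels) to the vertices of the outer
#' boundary contour. Zero for a disk; roughly the crack-arm protrusion
#' length when cracks radiate from the scar.
#'
#' @param region a [RegionImage-class] or logical mask.
#' @param normalize divide by the mean centroid-boundary distance
#'   (default FALSE: raw pixels).
#' @return Distance in pixels (or dimensionless if normalized).
#' @export
differentialDistance <- function(region, normalize = FALSE) {
  m <- .featureMask(region, "differential distance")
  cen <- colMeans(which(m, arr.ind = TRUE))
  ct <- .maskContour(m)
  d <- sqrt((ct$x - cen[1L])^2 + (ct$y - cen[2L])^2)
  out <- max(d) - min(d)
  if (normalize) out / mean(d) else out
}

#' Bundle the two shape descriptors for one sample
#'
#' @param region a [RegionImage-class] or logical mask.
#' @param sampleId sample identifier.
#' @param label class label, `"SOUND"` or `"CRACKED"`.
#' @param normalize passed to [differentialDistance].
#' @return One-row data.frame with columns sample_id, label, R, D.
#' @export
extractFeatures <- function(region, sampleId, label, normalize = FALSE) {
  data.frame(sample_id = sampleId, label = label,
             R = roundness(region),
             D = differentialDistance(region, normalize = normalize),
             stringsAsFactors = FALSE)
}

#' Write / read a shape-feature table (tab-delimited text)
#'
#' @param features data.frame with columns sample_id, label, R, D.
#' @param path file path.
#' @return `path` invisibly; the reader returns the data.frame.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
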