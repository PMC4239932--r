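#' Build a RegionImage from a binary mask
#'
#' Labels the 8-connected components of the mask (8-connectivity preserves
#' thin diagonal crack arms) and records per-component pixel counts.
#' Components are numbered 1..n in order of first appearance in a
#' row-major scan.
#'
#' @param mask logical matrix.
#' @return A [RegionImage-class].
#' @export
regionImage <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  lab <- .labelComponents8(mask)
  n <- attr(lab, "nComponents")
  sizes <- if (n > 0L) as.integer(tabulate(lab[lab > 0L], nbins = n))
           else integer(0)
  new("RegionImage", mask = mask, labels = lab, sizes = sizes)
}

#' Dark-region mask at the reflectance-maximum band
#'
#' Foreground = pixels darker than `cutoff` (default 30% reflectance) at
#' the band nearest `bandNm`, restricted to the fruit interior. The stem
#' scar and crack shadow are dark at 1098 nm while the fruit body is near
#' its reflectance peak, so this isolates the scar/crack zone. The fruit
#' interior is the hole-filled fruit mask (the dark scar itself would
#' otherwise punch a hole through the fruit mask).
#'
#' @param cube reflectance [HyperCube-class].
#' @param bandNm masking band (nm), default 1098.
#' @param cutoff reflectance threshold, default 0.30.
#' @param fruitThreshold threshold passed to [fruitMask] for the interior.
#' @return Logical matrix.
#' @export
reflectanceMask <- function(cube, bandNm = 1098, cutoff = 0.30,
                            fruitThreshold = 0.30) {
  stopifnot(is(cube, "HyperCube"))
  wl <- cube@wavelength
  if (bandNm < min(wl) || bandNm > max(wl))
    stop("masking band outside the cube's wavelength range")
  b <- nearestBand(cube, bandNm)
  inside <- suppressWarnings(fillHoles(fruitMask(cube, fruitThreshold,
                                                 bandNm)))
  (cube@data[, , b] < cutoff) & inside
}

#' Combine two binary masks (element-wise AND)
#'
#' @param a,b logical matrices of equal shape.
#' @return Logical matrix, `a & b`.
#' @export
combineMasks <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical shape")
  a & b
}

#' Fill interior holes of a binary mask
#'
#' Background components not connected to the raster border become
#' foreground; background touching any edge is exterior and is kept.
#'
#' @param mask logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fillHoles <- function(mask) {
  m <- as.matrix(mask)
  storage.mode(m) <- "numeric"
  filled <- EBImage::fillHull(m)
  filled > 0
}

#' Delete small components
#'
#' Removes connected components with fewer than `minPixels` pixels
#' (strict inequality: a 20-pixel component survives a 20-pixel rule).
#'
#' @param region a [RegionImage-class] or logical mask.
#' @param minPixels components smaller than this are dropped (default 20).
#' @return A [RegionImage-class].
#' @export
removeSmall <- function(region, minPixels = 20L) {
  if (!is(region, "RegionImage")) region <- regionImage(region)
  if (minPixels < 0L) stop("minPixels must be >= 0")
  drop <- which(region@sizes < minPixels)
  if (!length(drop)) return(region)
  mask <- region@mask
  mask[region@labels %in% drop] <- FALSE
  regionImage(mask)
}

#' Keep only the largest component
#'
#' Retains the maximum-size component; on ties, the component whose
#' minimum (row, col) pixel is lexicographically smallest wins. An empty
#' region stays empty.
#'
#' @param region a [RegionImage-class] or logical mask.
#' @return A [RegionImage-class].
#' @export
keepLargest <- function(region) {
  if (!is(region, "RegionImage")) region <- regionImage(region)
  if (!length(region@sizes)) return(region)
  big <- which(region@sizes == max(region@sizes))
  if (length(big) > 1L) {
    ## lexicographic (row, col) of each candidate's first pixel
    first <- t(vapply(big, function(l) {
      px <- which(region@labels == l, arr.ind = TRUE)
      px[order(px[, 1L], px[, 2L])[1L], ]
    }, integer(2)))
    big <- big[order(first[, 1L], first[, 2L])[1L]]
  }
  regionImage(region@labels == big)
}
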