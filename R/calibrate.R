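#' White/dark reflectance calibration
#'
#' Converts raw detector counts to relative reflectance,
#' \deqn{I = (I_0 - D) / (W - D),}
#' where \eqn{I_0} is the sample cube and \eqn{W}, \eqn{D} are white-panel
#' and dark-current reference cubes of the same geometry. Because the imager
#' is a line-scan instrument, each reference is first averaged over scan
#' lines (rows) to one reference line per (column, band) and then broadcast
#' down the scene — robust to scene-to-scene registration. Output is clipped
#' to [0, 1.5]: sound tissue lies in [0, ~1] while specular highlights may
#' legitimately exceed 1.
#'
#' @param raw sample [HyperCube-class] of kind `"counts"`.
#' @param white,dark reference cubes, same shape and wavelength grid.
#' @return A reflectance [HyperCube-class].
#' @examples
#' wl <- c(1000, 1100, 1200)
#' white <- HyperCube(array(4000, c(4, 4, 3)), wl, "counts")
#' dark  <- HyperCube(array(100,  c(4, 4, 3)), wl, "counts")
#' raw   <- HyperCube(array(2050, c(4, 4, 3)), wl, "counts")
#' calibrateReflectance(raw, white, dark)  # all 0.5
#' @export
calibrateReflectance <- function(raw, white, dark) {
  stopifnot(is(raw, "HyperCube"), is(white, "HyperCube"),
            is(dark, "HyperCube"))
  d <- dim(raw@data)
  if (!identical(d, dim(white@data)) || !identical(d, dim(dark@data)))
    stop("raw, white and dark cubes must share one shape")
  if (!isTRUE(all.equal(raw@wavelength, white@wavelength)) ||
      !isTRUE(all.equal(raw@wavelength, dark@wavelength)))
    stop("raw, white and dark cubes must share one wavelength grid")
  ## average references over scan lines -> (cols x bands)
  refW <- colMeans(white@data)               # cols x bands
  refD <- colMeans(dark@data)
  denom <- refW - refD
  if (any(denom <= 0)) {
    bad <- which(colSums(denom <= 0) > 0)[1L]
    stop(sprintf(
      "calibration error: white - dark <= 0 at band %d (%.1f nm)",
      bad, raw@wavelength[bad]))
  }
  ## broadcast references across rows
  expand <- function(m) aperm(array(m, c(d[2], d[3], d[1])), c(3, 1, 2))
  refl <- (raw@data - expand(refD)) / expand(denom)
  refl <- pmin(pmax(refl, 0), 1.5)
  HyperCube(refl, raw@wavelength, kind = "reflectance")
}

#' Index of the band nearest a target wavelength
#'
#' Returns the 1-based band index minimizing |wavelength - target|; ties go
#' to the lower index. On the instrument's 144-band 1000-1700 nm grid
#' (~4.9 nm spacing) the reflectance-maximum band used for masking is the
#' one nearest 1098 nm.
#'
#' @param object a [HyperCube-class], [LabeledSpectra-class], or numeric
#'   wavelength vector.
#' @param targetNm target wavelength in nm.
#' @return Integer band index (1-based).
#' @examples
#' nearestBand(seq(1000, 1700, length.out = 144), 1098)  # 21
#' @export
nearestBand <- function(object, targetNm) {
  wl <- if (is.numeric(object)) object else wavelengths(object)
  if (!length(wl)) stop("empty wavelength grid")
  which.min(abs(wl - targetNm))
}
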