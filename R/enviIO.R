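## ENVI raster I/O: flat binary cube + text header. Supported dialect:
## interleaves BSQ/BIL/BIP, little-endian, data types 1 (uint8),
## 4 (float32), 12 (uint16). Cubes are written BIL/float32.

.enviHeaderPath <- function(path) {
  if (grepl("\\.hdr$", path)) return(path)
  hdr <- paste0(path, ".hdr")
  if (file.exists(hdr)) return(hdr)
  alt <- sub("\\.[^.]+$", ".hdr", path)
  if (file.exists(alt)) return(alt)
  hdr
}

.parseEnviHeader <- function(hdrPath) {
  if (!file.exists(hdrPath))
    stop("ENVI header not found: ", hdrPath)
  txt <- readLines(hdrPath, warn = FALSE)
  full <- paste(txt, collapse = "\n")
  getKey <- function(key, numeric = TRUE) {
    pat <- paste0("(?mi)^\\s*", key, "\\s*=\\s*([^\\n{]+)$")
    m <- regmatches(full, regexpr(pat, full, perl = TRUE))
    if (!length(m)) return(NULL)
    val <- trimws(sub(pat, "\\1", m, perl = TRUE))
    if (numeric) as.numeric(val) else val
  }
  getBlock <- function(key) {
    pat <- paste0("(?si)", key, "\\s*=\\s*\\{(.*?)\\}")
    m <- regmatches(full, regexpr(pat, full, perl = TRUE))
    if (!length(m)) return(NULL)
    body <- sub(pat, "\\1", m, perl = TRUE)
    as.numeric(strsplit(gsub("[\\n\\r]", " ", body), ",")[[1L]])
  }
  hdr <- list(
    samples    = getKey("samples"),
    lines      = getKey("lines"),
    bands      = getKey("bands"),
    dataType   = getKey("data type"),
    byteOrder  = getKey("byte order"),
    interleave = toupper(getKey("interleave", numeric = FALSE) %||% "BSQ"),
    wavelength = getBlock("wavelength"),
    kind       = getKey("cube kind", numeric = FALSE))
  for (k in c("samples", "lines", "bands", "dataType"))
    if (is.null(hdr[[k]]) || is.na(hdr[[k]]))
      stop("ENVI header missing required key: ", k)
  hdr
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

.enviTypeInfo <- function(dataType) {
  switch(as.character(dataType),
    "1"  = list(what = "integer", size = 1L, signed = FALSE),
    "4"  = list(what = "numeric", size = 4L, signed = TRUE),
    "12" = list(what = "integer", size = 2L, signed = FALSE),
    stop("unsupported ENVI data type: ", dataType,
         " (supported: 1, 4, 12)"))
}

#' Read an ENVI hyperspectral cube
#'
#' Reads a flat-binary ENVI raster with its text header. The header must
#' carry a `wavelength { ... }` block whose length matches the band count;
#' interleave may be BSQ, BIL or BIP; data types 1 (uint8), 4 (float32) and
#' 12 (uint16) are supported, little-endian.
#'
#' @param path path to the binary file (a sibling `.hdr` is located
#'   automatically) or directly to the header.
#' @return A [HyperCube-class]; `kind` is taken from the optional
#'   `cube kind` header key, defaulting to `"reflectance"` for float data
#'   and `"counts"` for integer data.
#' @seealso [writeENVI]
#' @export
readENVI <- function(path) {
  hdrPath <- .enviHeaderPath(path)
  binPath <- if (grepl("\\.hdr$", path)) sub("\\.hdr$", "", path) else path
  hdr <- .parseEnviHeader(hdrPath)
  if (is.null(hdr$wavelength))
    stop("ENVI header has no wavelength block; cannot build a HyperCube")
  if (length(hdr$wavelength) != hdr$bands)
    stop(sprintf("ENVI header mismatch: %d wavelengths for %d bands",
                 length(hdr$wavelength), hdr$bands))
  if (!is.null(hdr$byteOrder) && !is.na(hdr$byteOrder) && hdr$byteOrder != 0)
    stop("only little-endian (byte order = 0) ENVI files are supported")
  ti <- .enviTypeInfo(hdr$dataType)
  n <- hdr$samples * hdr$lines * hdr$bands
  expect <- n * ti$size
  if (file.info(binPath)$size != expect)
    stop(sprintf("ENVI data size mismatch: expected %d bytes, found %d",
                 expect, file.info(binPath)$size))
  con <- file(binPath, "rb"); on.exit(close(con))
  v <- readBin(con, ti$what, n = n, size = ti$size, signed = ti$signed,
               endian = "little")
  a <- switch(hdr$interleave,
    BSQ = aperm(array(v, c(hdr$samples, hdr$lines, hdr$bands)), c(2, 1, 3)),
    BIL = aperm(array(v, c(hdr$samples, hdr$bands, hdr$lines)), c(3, 1, 2)),
    BIP = aperm(array(v, c(hdr$bands, hdr$samples, hdr$lines)), c(3, 2, 1)),
    stop("unsupported interleave: ", hdr$interleave))
  kind <- hdr$kind %||% if (ti$what == "numeric") "reflectance" else "counts"
  HyperCube(a * 1.0, hdr$wavelength, kind = kind)
}

#' Write an ENVI hyperspectral cube
#'
#' @param cube a [HyperCube-class].
#' @param path output path for the binary file; `path.hdr` is written
#'   alongside.
#' @param interleave one of `"bil"` (default), `"bsq"`, `"bip"`.
#' @param dataType ENVI data type code: 4 (float32, default), 12 (uint16)
#'   or 1 (uint8).
#' @return `path`, invisibly.
#' @export
writeENVI <- function(cube, path, interleave = c("bil", "bsq", "bip"),
                      dataType = 4L) {
  stopifnot(is(cube, "HyperCube"))
  interleave <- match.arg(interleave)
  ti <- .enviTypeInfo(dataType)
  d <- dim(cube@data)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube@data, c(2, 1, 3))),
    bil = as.vector(aperm(cube@data, c(2, 3, 1))),
    bip = as.vector(aperm(cube@data, c(3, 2, 1))))
  con <- file(path, "wb")
  if (ti$what == "integer") {
    writeBin(as.integer(round(v)), con, size = ti$size, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = ti$size, endian = "little")
  }
  close(con)
  hdr <- c("ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dataType),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("cube kind = %s", cube@kind),
    sprintf("wavelength = {\n %s\n}",
            paste(format(cube@wavelength, trim = TRUE),
                  collapse = ",\n ")))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read / write single-band 8-bit label rasters (ENVI)
#'
#' Label rasters carry ROI codes 0 = unlabeled, 1 = sound, 2 = crack,
#' 3 = stem scar, 4 = specular (masks use 0/1). Stored as ENVI uint8,
#' single band, no wavelength block required.
#'
#' @param m integer matrix of pixel codes.
#' @param path raster path (binary; `.hdr` sibling handled automatically).
#' @return `readLabelRaster`: an integer matrix; `writeLabelRaster`:
#'   `path`, invisibly.
#' @export
writeLabelRaster <- function(m, path) {
  m <- as.matrix(m)
  con <- file(path, "wb")
  writeBin(as.integer(as.vector(t(m))), con, size = 1L, endian = "little")
  close(con)
  hdr <- c("ENVI",
    sprintf("samples = %d", ncol(m)),
    sprintf("lines = %d", nrow(m)),
    "bands = 1", "header offset = 0", "file type = ENVI Standard",
    "data type = 1", "interleave = bsq", "byte order = 0")
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname writeLabelRaster
#' @export
readLabelRaster <- function(path) {
  hdr <- .parseEnviHeader(.enviHeaderPath(path))
  binPath <- if (grepl("\\.hdr$", path)) sub("\\.hdr$", "", path) else path
  if (hdr$bands != 1L) stop("label rasters must be single-band")
  ti <- .enviTypeInfo(hdr$dataType)
  con <- file(binPath, "rb"); on.exit(close(con))
  v <- readBin(con, ti$what, n = hdr$samples * hdr$lines, size = ti$size,
               signed = ti$signed, endian = "little")
  matrix(as.integer(v), nrow = hdr$lines, ncol = hdr$samples, byrow = TRUE)
}
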