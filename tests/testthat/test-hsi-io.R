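test_that("ENVI write/read round-trips values and wavelengths for all interleaves", {
  wl <- c(1000, 1250, 1500)
  set.seed(42)
  cube <- HyperCube(array(runif(4 * 4 * 3), c(4, 4, 3)), wl)
  for (il in c("bil", "bsq", "bip")) {
    path <- file.path(withr::local_tempdir(), paste0("cube_", il, ".dat"))
    writeENVI(cube, path, interleave = il)
    back <- readENVI(path)
    expect_equal(cubeData(back), cubeData(cube), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(wavelengths(back), wl, tolerance = 1e-9)
    expect_identical(back@kind, "reflectance")
  }
})

test_that("uint16 cubes survive a round trip exactly", {
  wl <- c(1100, 1200)
  cube <- HyperCube(array(c(0, 7, 65535, 123, 4096, 9), c(1, 3, 2)),
                    wl, kind = "counts")
  path <- file.path(withr::local_tempdir(), "u16.dat")
  writeENVI(cube, path, dataType = 12L)
  back <- readENVI(path)
  expect_identical(back@kind, "counts")
  expect_equal(cubeData(back), cubeData(cube), ignore_attr = TRUE)
})

test_that("header/data mismatches are format errors", {
  wl <- seq(1000, 1700, length.out = 4)
  cube <- HyperCube(array(0.5, c(3, 3, 4)), wl)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cube.dat")
  writeENVI(cube, path)

  # header claims one wavelength too many
  hdr <- readLines(paste0(path, ".hdr"))
  hdr <- sub("^bands = 4", "bands = 5", hdr)
  writeLines(hdr, paste0(path, ".hdr"))
  expect_error(readENVI(path), "mismatch")

  # header without a wavelength block
  writeENVI(cube, path)
  hdr <- readLines(paste0(path, ".hdr"))
  drop <- grep("wavelength|^ 1|^\\}", hdr)
  writeLines(hdr[-drop], paste0(path, ".hdr"))
  expect_error(readENVI(path), "wavelength")
})

test_that("BIL bytes laid out by hand land in the right voxels", {
  # 2 lines x 2 samples x 2 bands, float32 little-endian BIL:
  # line 1 [band 1: s1 s2][band 2: s1 s2], then line 2.
  dir <- withr::local_tempdir()
  path <- file.path(dir, "hand.dat")
  vals <- c(111, 112, 121, 122,   # line 1: b1(s1,s2), b2(s1,s2)
            211, 212, 221, 222)   # line 2
  con <- file(path, "wb")
  writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  close(con)
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 2",
               "data type = 4", "interleave = bil", "byte order = 0",
               "wavelength = { 1000, 1500 }"), paste0(path, ".hdr"))
  cube <- readENVI(path)
  d <- cubeData(cube)
  # d[line, sample, band] should be 100*line + 10*band + sample
  for (l in 1:2) for (s in 1:2) for (b in 1:2)
    expect_equal(d[l, s, b], 100 * l + 10 * b + s)
})

test_that("label rasters round-trip", {
  m <- matrix(sample(0:4, 30, replace = TRUE), 5, 6)
  path <- file.path(withr::local_tempdir(), "roi.dat")
  writeLabelRaster(m, path)
  expect_identical(readLabelRaster(path), m)
})

test_that("reflectance calibration reproduces the flat-field identities", {
  wl <- seq(1000, 1700, length.out = 5)
  mk <- function(v) HyperCube(array(v, c(4, 3, 5)), wl, "counts")
  white <- mk(4000); dark <- mk(200)
  expect_equal(cubeData(calibrateReflectance(white, white, dark)),
               array(1, c(4, 3, 5)))
  expect_equal(cubeData(calibrateReflectance(dark, white, dark)),
               array(0, c(4, 3, 5)))
  mid <- mk((4000 + 200) / 2)
  expect_equal(cubeData(calibrateReflectance(mid, white, dark)),
               array(0.5, c(4, 3, 5)))
})

test_that("calibration is invariant to a common positive gain", {
  wl <- seq(1000, 1700, length.out = 6)
  set.seed(7)
  raw <- HyperCube(array(runif(60, 500, 3000), c(2, 5, 6)), wl, "counts")
  white <- HyperCube(array(runif(60, 3500, 4000), c(2, 5, 6)), wl, "counts")
  dark <- HyperCube(array(runif(60, 50, 150), c(2, 5, 6)), wl, "counts")
  scale <- function(cube, g) HyperCube(cubeData(cube) * g, wl, "counts")
  r1 <- calibrateReflectance(raw, white, dark)
  r2 <- calibrateReflectance(scale(raw, 3.7), scale(white, 3.7),
                             scale(dark, 3.7))
  expect_equal(cubeData(r1), cubeData(r2), tolerance = 1e-12)
})

test_that("calibration rejects non-positive white-dark denominators, naming the band", {
  wl <- c(1000, 1350, 1700)
  white <- HyperCube(array(1000, c(2, 2, 3)), wl, "counts")
  d <- array(100, c(2, 2, 3)); d[, , 2] <- 1000
  dark <- HyperCube(d, wl, "counts")
  raw <- HyperCube(array(500, c(2, 2, 3)), wl, "counts")
  expect_error(calibrateReflectance(raw, white, dark), "band 2")
})

test_that("references are averaged over scan lines before use", {
  # white varies across rows; its row-mean defines the reference line
  wl <- c(1000, 1700)
  w <- array(0, c(2, 1, 2)); w[1, 1, ] <- 900; w[2, 1, ] <- 1100
  white <- HyperCube(w, wl, "counts")
  dark <- HyperCube(array(0, c(2, 1, 2)), wl, "counts")
  raw <- HyperCube(array(500, c(2, 1, 2)), wl, "counts")
  out <- calibrateReflectance(raw, white, dark)
  expect_equal(as.vector(cubeData(out)), rep(0.5, 4))  # 500/1000
})

test_that("specular pixels are clipped at 1.5 after calibration", {
  wl <- c(1000, 1700)
  white <- HyperCube(array(1000, c(1, 1, 2)), wl, "counts")
  dark <- HyperCube(array(0, c(1, 1, 2)), wl, "counts")
  raw <- HyperCube(array(2500, c(1, 1, 2)), wl, "counts")
  expect_equal(as.vector(cubeData(calibrateReflectance(raw, white, dark))),
               c(1.5, 1.5))
})

test_that("nearestBand matches exhaustive search and breaks ties downward", {
  grid144 <- seq(1000, 1700, length.out = 144)
  expect_identical(nearestBand(grid144, 1098), 21L)   # band spacing ~4.9 nm
  expect_identical(nearestBand(grid144, grid144[77]), 77L)
  expect_identical(nearestBand(c(1000, 1010), 1005), 1L)  # tie -> lower

  set.seed(11)
  for (i in 1:1000) {
    wl <- sort(runif(sample(2:30, 1), 1000, 1700))
    wl <- wl[!duplicated(wl)]
    target <- runif(1, 950, 1750)
    idx <- nearestBand(wl, target)
    brute <- which(abs(wl - target) == min(abs(wl - target)))[1L]
    expect_identical(idx, brute)
  }
})
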