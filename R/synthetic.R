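## Synthetic tomato-phantom scenes.
##
## Each scene is a fruit disk on a dark stage background carrying a
## central stem scar (elliptical, with a rough boundary), optional radial
## crack arms emanating from the scar, and 1-2 specular highlight blobs.
## Per-pixel spectra are region endmembers modulated by a multiplicative
## lognormal texture (per pixel) and additive sensor noise (per voxel,
## fruit pixels). The scar and its crack arms sit in a concave, shadowed
## zone and are rendered dark near 1098 nm; crack tissue is brighter than
## sound tissue at longer wavelengths (shallower water absorption).

.gaussBump <- function(wl, mu, sigma) exp(-0.5 * ((wl - mu) / sigma)^2)

#' Default region endmember spectra
#'
#' Smooth spectra over the 1000-1700 nm grid built from a broad arch
#' (reflectance maximum near 1098 nm) minus Gaussian water-absorption
#' wells at 1190 and 1450 nm. Cracked cuticle is drier than sound tissue,
#' so its wells are much shallower — a property it shares with specular
#' highlights (illuminant reflection dilutes tissue absorption), which is
#' exactly why a crack-vs-sound discriminant lets specular pixels through
#' while a crack-vs-specular discriminant suppresses them. Levels at
#' 1098 nm: specular ~1.25, sound ~0.6, crack ~0.22 and stem ~0.17 (the
#' scar concavity and the fissures radiating from it sit in a shadow
#' notch around 1098 nm); away from the notch the crack spectrum exceeds
#' the sound spectrum, and the specular spectrum exceeds everything at
#' every band. The stem-scar spectrum is a dimmed copy of the crack
#' spectrum (same dry, shadowed tissue), which is what makes the scar
#' score crack-like in both PLS-DA variants.
#'
#' @param wavelength band grid (nm); must span roughly 1000-1700 nm.
#' @param textureSd sd of the multiplicative lognormal texture
#'   (default 0.05).
#' @param noiseSd sd of the additive per-voxel sensor noise
#'   (default 0.01).
#' @return An [EndmemberSet-class].
#' @export
defaultEndmembers <- function(wavelength, textureSd = 0.05,
                              noiseSd = 0.01) {
  wl <- as.numeric(wavelength)
  if (min(wl) > 1100 || max(wl) < 1500)
    stop("wavelength grid must span roughly 1000-1700 nm")
  arch <- 1 - ((wl - 1098) / 900)^2
  flat <- 1 - ((wl - 1200) / 1400)^2
  g1190 <- .gaussBump(wl, 1190, 28)
  g1450 <- .gaussBump(wl, 1450, 55)
  notch <- .gaussBump(wl, 1098, 18)
  crackShape <- 0.72 * arch * (1 - 0.10 * g1190 - 0.20 * g1450) *
    (1 - 0.70 * notch)
  sp <- rbind(
    SOUND    = 0.62 * arch * (1 - 0.30 * g1190 - 0.55 * g1450),
    CRACK    = crackShape,
    STEM     = 0.78 * crackShape * (1 - 0.05 * g1190 - 0.08 * g1450),
    SPECULAR = 1.28 * flat * (1 - 0.06 * g1190 - 0.10 * g1450))
  new("EndmemberSet", spectra = sp, background = 0.05 * flat,
      wavelength = wl, textureSd = textureSd, noiseSd = noiseSd)
}

#' Phantom scene configuration
#'
#' Geometry and noise parameters of one synthetic scene. Defaults
#' reproduce the study's imaging geometry (320 x 420 pixels, 144 bands
#' over 1000-1700 nm, one fruit per scene) with scar/crack statistics
#' frozen after a one-time difficulty calibration (see the package
#' vignette). Two-element vectors are uniform sampling ranges.
#'
#' @param rows,cols,bands image geometry.
#' @param wlMin,wlMax wavelength span (nm).
#' @param fruitRadius fruit-disk radius range (px).
#' @param fruitJitter max offset of the fruit center from the image
#'   center (px).
#' @param scarRadius stem-scar mean radius range (px).
#' @param scarAxisRatio scar ellipse axis-ratio range.
#' @param scarJitter max scar offset from the fruit center (px).
#' @param scarRoughness relative amplitude range of the smooth periodic
#'   boundary roughness.
#' @param scarHarmonics angular frequencies available to the roughness.
#' @param scarLobes number of narrow scar-boundary lobes (stem-tissue
#'   protrusions, drawn for both classes; sampled from this set). Lobes
#'   are what makes roundness alone an unreliable discriminant, as on
#'   real stem scars.
#' @param scarLobeHeight lobe radial height range (px).
#' @param scarLobeWidth lobe angular half-width range (radians).
#' @param scarSpanCap upper bound on the scar boundary's radial span
#'   (max - min distance from the scar center, px): stem-scar
#'   irregularity is bounded, while crack arms extend beyond it. Lobe
#'   and roughness deviations are rescaled when they would exceed it.
#' @param scarSutures number of radial suture ridges (benign stem-tissue
#'   lines radiating from the scar, present on sound and cracked fruit;
#'   sampled from this set). Sutures carry crack-like boundary length but
#'   only bounded radial extent, which is why roundness alone is a weak
#'   discriminant while the differential distance still separates.
#' @param sutureLength,sutureWidth suture ridge protrusion length and
#'   width ranges (px).
#' @param crackArms number of crack arms drawn for CRACKED scenes
#'   (sampled from this set).
#' @param crackLength protrusion length range of the primary crack arm
#'   beyond the scar boundary (px).
#' @param crackSecondaryLength protrusion length range of any additional
#'   (secondary) fissure arms (px).
#' @param crackWidth arm width range (px).
#' @param specularCount number of specular blobs (sampled from this set).
#' @param specularRadius specular blob radius range (px).
#' @param textureSd,noiseSd noise parameters (see [defaultEndmembers]).
#' @param label scene class, `"SOUND"` or `"CRACKED"`.
#' @param seed integer RNG seed for the scene.
#' @return A named list (class `"phantomConfig"`).
#' @export
phantomConfig <- function(rows = 320L, cols = 420L, bands = 144L,
                          wlMin = 1000, wlMax = 1700,
                          fruitRadius = c(105, 125), fruitJitter = 10,
                          scarRadius = c(16, 24),
                          scarAxisRatio = c(1, 1.2), scarJitter = 8,
                          scarRoughness = c(0.05, 0.16),
                          scarHarmonics = 9:16,
                          scarLobes = 0:3,
                          scarLobeHeight = c(2, 5),
                          scarLobeWidth = c(0.05, 0.12),
                          scarSpanCap = 6,
                          scarSutures = 1:4,
                          sutureLength = c(6, 10),
                          sutureWidth = c(2, 3),
                          crackArms = 1:3,
                          crackLength = c(16, 24),
                          crackSecondaryLength = c(4, 12),
                          crackWidth = c(2, 4),
                          specularCount = 1:2, specularRadius = c(8, 15),
                          textureSd = 0.05, noiseSd = 0.01,
                          label = "SOUND", seed = 1L) {
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              bands = as.integer(bands), wlMin = wlMin, wlMax = wlMax,
              fruitRadius = fruitRadius, fruitJitter = fruitJitter,
              scarRadius = scarRadius, scarAxisRatio = scarAxisRatio,
              scarJitter = scarJitter, scarRoughness = scarRoughness,
              scarHarmonics = scarHarmonics, scarLobes = scarLobes,
              scarLobeHeight = scarLobeHeight,
              scarLobeWidth = scarLobeWidth, scarSpanCap = scarSpanCap,
              scarSutures = scarSutures, sutureLength = sutureLength,
              sutureWidth = sutureWidth,
              crackArms = crackArms,
              crackLength = crackLength,
              crackSecondaryLength = crackSecondaryLength,
              crackWidth = crackWidth,
              specularCount = specularCount,
              specularRadius = specularRadius,
              textureSd = textureSd, noiseSd = noiseSd,
              label = label, seed = as.integer(seed))
  class(cfg) <- "phantomConfig"
  cfg
}

.runif1 <- function(range) stats::runif(1L, range[1L], range[2L])

#' Render one phantom scene
#'
#' Deterministic for a fixed config seed. Geometry: fruit disk near the
#' image center; elliptical rough-edged scar at the fruit center; for
#' CRACKED scenes 1-3 radial crack arms emanating from the scar; specular
#' blobs on the fruit body away from the scar zone. See the class docs
#' for truth codes.
#'
#' @param config a [phantomConfig] list.
#' @param endmembers optional [EndmemberSet-class]; defaults to
#'   [defaultEndmembers] on the config's grid.
#' @return A [PhantomScene-class].
#' @export
renderScene <- function(config, endmembers = NULL) {
  stopifnot(inherits(config, "phantomConfig"))
  cfg <- config
  wl <- seq(cfg$wlMin, cfg$wlMax, length.out = cfg$bands)
  em <- if (is.null(endmembers))
    defaultEndmembers(wl, cfg$textureSd, cfg$noiseSd) else endmembers
  nr <- cfg$rows; nc <- cfg$cols

  withr::with_seed(cfg$seed, {
    truth <- .drawTruth(cfg)

    ## spectra: endmember x lognormal texture (+ sensor noise on fruit).
    ## The cube dominates run time; keep it to one big allocation plus
    ## in-place-ish ops, and confine additive noise and clipping to the
    ## fruit rows (background texture cannot leave [0, 1.5]).
    Em <- rbind(em@background, em@spectra[REGION_LEVELS, , drop = FALSE])
    tex <- stats::rlnorm(nr * nc, meanlog = -em@textureSd^2 / 2,
                         sdlog = em@textureSd)
    X <- Em[as.vector(truth) + 1L, , drop = FALSE] * tex
    fruitIdx <- which(as.vector(truth) > 0L)
    if (length(fruitIdx) && em@noiseSd > 0) {
      Xf <- X[fruitIdx, , drop = FALSE]
      Xf <- Xf * (1 + stats::rnorm(length(Xf), 0, em@noiseSd))
      X[fruitIdx, ] <- pmin(pmax(Xf, 0), 1.5)
    }
    dim(X) <- c(nr, nc, cfg$bands)
    cube <- HyperCube(X, wl, kind = "reflectance")
    new("PhantomScene", cube = cube, truth = truth, label = cfg$label,
        config = unclass(cfg), seed = cfg$seed)
  })
}

#' Ground-truth raster of a phantom scene without rendering spectra
#'
#' Draws the same geometry (same RNG stream) as [renderScene] but skips
#' the spectral cube — useful for geometry-level analyses and tests.
#'
#' @param config a [phantomConfig] list.
#' @return Integer truth matrix (codes as in [PhantomScene-class]).
#' @export
renderTruth <- function(config) {
  stopifnot(inherits(config, "phantomConfig"))
  withr::with_seed(config$seed, .drawTruth(config))
}

## geometry draw; must run inside an established RNG context
.drawTruth <- function(cfg) {
  nr <- cfg$rows; nc <- cfg$cols
  maxFruit <- max(cfg$fruitRadius) + cfg$fruitJitter
  if (2 * maxFruit >= min(nr, nc))
    stop("geometry overflow: fruit does not fit inside the image")
  {
    fruitR <- .runif1(cfg$fruitRadius)
    fc <- c(nr, nc) / 2 + stats::runif(2L, -cfg$fruitJitter,
                                       cfg$fruitJitter)
    sc <- fc + stats::runif(2L, -cfg$scarJitter, cfg$scarJitter)

    row <- matrix(seq_len(nr), nr, nc)
    col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    fruit <- (row - fc[1L])^2 + (col - fc[2L])^2 <= fruitR^2

    ## scar boundary: ellipse radius modulated by smooth periodic
    ## roughness
    m <- .runif1(cfg$scarRadius)
    q <- .runif1(cfg$scarAxisRatio)
    a <- m * sqrt(q); b <- m / sqrt(q)
    th0 <- stats::runif(1L, 0, pi)
    ## one dominant waviness harmonic: the relative amplitude rho sets
    ## both the radial excursion (rho * radius) and, with the angular
    ## frequency, the perimeter inflation
    rho <- .runif1(cfg$scarRoughness)
    nh <- 1L
    harm <- if (length(cfg$scarHarmonics) == 1L) cfg$scarHarmonics
            else sample(cfg$scarHarmonics, nh)
    amp <- rho
    ph <- stats::runif(nh, 0, 2 * pi)
    ## drawn for both labels so matched seeds share the scar geometry
    nArmsDraw <- if (length(cfg$crackArms) == 1L) cfg$crackArms
                 else sample(cfg$crackArms, 1L)
    nArms <- if (cfg$label == "CRACKED") nArmsDraw else 0L
    nLobes <- if (length(cfg$scarLobes) == 1L) cfg$scarLobes
              else sample(cfg$scarLobes, 1L)
    lobeAng <- stats::runif(max(nLobes, 1L), 0, 2 * pi)[seq_len(nLobes)]
    lobeH <- stats::runif(max(nLobes, 1L), cfg$scarLobeHeight[1L],
                          cfg$scarLobeHeight[2L])[seq_len(nLobes)]
    lobeW <- stats::runif(max(nLobes, 1L), cfg$scarLobeWidth[1L],
                          cfg$scarLobeWidth[2L])[seq_len(nLobes)]
    scarRadiusRaw <- function(phi) {
      pe <- phi - th0
      re <- a * b / sqrt((b * cos(pe))^2 + (a * sin(pe))^2)
      rough <- rep(1, length(phi))
      for (h in seq_len(nh))
        rough <- rough + amp[h] * sin(harm[h] * phi + ph[h])
      r <- re * rough
      for (l in seq_len(nLobes)) {
        dphi <- (phi - lobeAng[l] + pi) %% (2 * pi) - pi
        r <- r + lobeH[l] * exp(-0.5 * (dphi / lobeW[l])^2)
      }
      r
    }
    ## bound the scar's radial span: irregularity stays within
    ## scarSpanCap, so only crack arms can reach beyond it
    grid <- scarRadiusRaw(seq(0, 2 * pi, length.out = 720L))
    rMin <- min(grid)
    span <- max(grid) - rMin
    shrink <- if (span > cfg$scarSpanCap) cfg$scarSpanCap / span else 1
    scarRadiusAt <- function(phi)
      rMin + (scarRadiusRaw(phi) - rMin) * shrink

    dr <- row - sc[1L]; dc <- col - sc[2L]
    dist <- sqrt(dr^2 + dc^2)
    phi <- atan2(dc, dr)
    scar <- dist <= scarRadiusAt(phi)

    ## radial features: every fruit carries 1-3 suture ridges (benign
    ## stem tissue); on a cracked fruit, the crack arms are sutures that
    ## have opened into fissures reaching beyond the bounded scar span
    nSutures <- if (length(cfg$scarSutures) == 1L) cfg$scarSutures
                else sample(cfg$scarSutures, 1L)
    nShort <- max(0L, nSutures - nArms)
    nFeat <- nArms + nShort
    radialMask <- function(ang, L, w) {
      along <- dr * cos(ang) + dc * sin(ang)
      perp <- abs(-dr * sin(ang) + dc * cos(ang))
      edge <- scarRadiusAt(rep(ang, 1L))
      along >= 0 & along <= edge + L & perp <= w / 2 & !scar
    }
    crack <- matrix(FALSE, nr, nc)
    suture <- matrix(FALSE, nr, nc)
    if (nFeat > 0L) {
      angles <- stats::runif(1L, 0, 2 * pi) +
        (seq_len(nFeat) - 1L) * 2 * pi / nFeat +
        stats::runif(nFeat, -0.3, 0.3)
      primary <- TRUE
      for (k in seq_len(nFeat)) {
        if (k <= nArms) {
          L <- if (primary) .runif1(cfg$crackLength)
               else .runif1(cfg$crackSecondaryLength)
          primary <- FALSE
          crack <- crack | radialMask(angles[k], L, .runif1(cfg$crackWidth))
        } else {
          suture <- suture |
            radialMask(angles[k], .runif1(cfg$sutureLength),
                       .runif1(cfg$sutureWidth))
        }
      }
    }
    if (cfg$label == "CRACKED" && !any(crack))
      stop("degenerate cracked scene: no crack pixels rendered")

    specular <- matrix(FALSE, nr, nc)
    nSpec <- if (length(cfg$specularCount) == 1L) cfg$specularCount
             else sample(cfg$specularCount, 1L)
    exclusion <- m * (1 + max(cfg$scarRoughness)) +
      max(cfg$crackLength) + max(cfg$specularRadius) + 4
    for (k in seq_len(nSpec)) {
      for (try in 1:50) {
        br <- .runif1(cfg$specularRadius)
        bd <- stats::runif(1L, 0.45, 0.80) * fruitR
        ba <- stats::runif(1L, 0, 2 * pi)
        bc <- fc + bd * c(cos(ba), sin(ba))
        if (sqrt(sum((bc - sc)^2)) > exclusion &&
            bd + br < fruitR - 2) break
      }
      specular <- specular |
        ((row - bc[1L])^2 + (col - bc[2L])^2 <= br^2)
    }
    specular <- specular & fruit & !scar & !crack & !suture

    truth <- matrix(0L, nr, nc)
    truth[fruit] <- 1L
    truth[specular] <- 4L
    truth[scar] <- 3L
    truth[suture] <- 3L
    truth[crack] <- 2L
    truth
  }
}

#' Generate a phantom benchmark manifest
#'
#' Draws distinct per-scene seeds from a master seed for `nSound` sound
#' and `nCracked` cracked scenes (defaults mirror the study's balanced
#' 112 + 112 design). Scenes are rendered lazily: a full-size benchmark
#' would occupy ~35 GB if materialized at once.
#'
#' @param nSound,nCracked scenes per class.
#' @param seed master seed.
#' @param config shared [phantomConfig] (its label/seed fields are
#'   overridden per scene).
#' @return A [PhantomBenchmark-class].
#' @export
generateBenchmark <- function(nSound = 112L, nCracked = 112L, seed = 101L,
                              config = phantomConfig()) {
  stopifnot(nSound >= 1L, nCracked >= 1L)
  n <- nSound + nCracked
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L, n))
  manifest <- data.frame(
    scene_id = sprintf("scene%03d", seq_len(n)),
    label = rep(c("SOUND", "CRACKED"), c(nSound, nCracked)),
    seed = seeds, stringsAsFactors = FALSE)
  new("PhantomBenchmark", manifest = manifest, config = unclass(config),
      seed = as.integer(seed))
}

#' Materialize one scene of a benchmark
#'
#' @param bench a [PhantomBenchmark-class].
#' @param i scene index (row of the manifest).
#' @param endmembers optional [EndmemberSet-class] override.
#' @return A [PhantomScene-class].
#' @export
benchmarkScene <- function(bench, i, endmembers = NULL) {
  stopifnot(is(bench, "PhantomBenchmark"))
  row <- bench@manifest[i, ]
  cfg <- bench@config
  cfg$label <- row$label
  cfg$seed <- as.integer(row$seed)
  class(cfg) <- "phantomConfig"
  renderScene(cfg, endmembers = endmembers)
}

#' Write a scene to disk (ENVI cube + truth raster + sidecar config)
#'
#' @param scene a [PhantomScene-class].
#' @param dir output directory (created if needed).
#' @param name basename for the three files.
#' @return The directory, invisibly.
#' @export
writeScene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeENVI(scene@cube, file.path(dir, paste0(name, ".dat")))
  writeLabelRaster(scene@truth, file.path(dir, paste0(name, "_truth.dat")))
  cfg <- scene@config
  keys <- vapply(cfg, function(v) paste(format(v, trim = TRUE),
                                        collapse = ","), "")
  writeLines(paste0(names(cfg), "=", keys),
             file.path(dir, paste0(name, "_config.txt")))
  invisible(dir)
}
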