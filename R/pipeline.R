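#' End-to-end pipeline configuration
#'
#' Thresholds and seeds of the full detection chain. Defaults are the
#' study's operating point: PLS-DA binarization at 0.5, 30% reflectance
#' mask at 1098 nm, removal of components under 20 pixels, 1000 training
#' spectra per region, 75/25 calibration/validation split, and the
#' crack-vs-specular PLS-DA variant.
#'
#' @param variant `"crack_vs_specular"` (default: suppresses specular
#'   highlights) or `"crack_vs_sound"` (the variant that leaves specular
#'   false positives).
#' @param scoreThreshold PLS-DA binarization threshold.
#' @param maskBandNm,maskCutoff reflectance-mask band (nm) and cutoff.
#' @param fruitThreshold fruit-mask threshold at the masking band.
#' @param minPixels components smaller than this are deleted.
#' @param spectraPerClass training spectra sampled per region.
#' @param maxK largest PLS latent-variable count considered.
#' @param splitFraction calibration fraction of the feature split.
#' @param nTrainScenes benchmark scenes (split evenly between classes)
#'   used to harvest training spectra.
#' @param nSound,nCracked benchmark scene counts per class.
#' @param samplingSeed,rmsevSeed,splitSeed,benchmarkSeed seeds for spectra
#'   sampling, the RMSEV split, the classifier split, and the benchmark
#'   manifest.
#' @param phantom a [phantomConfig] list for scene rendering.
#' @return A named list (class `"pipelineConfig"`).
#' @export
pipelineConfig <- function(variant = c("crack_vs_specular",
                                       "crack_vs_sound"),
                           scoreThreshold = 0.5, maskBandNm = 1098,
                           maskCutoff = 0.30, fruitThreshold = 0.30,
                           minPixels = 20L, spectraPerClass = 1000L,
                           maxK = 20L, splitFraction = 0.75,
                           nTrainScenes = 16L,
                           nSound = 112L, nCracked = 112L,
                           samplingSeed = 11L, rmsevSeed = 12L,
                           splitSeed = 13L, benchmarkSeed = 101L,
                           phantom = phantomConfig()) {
  variant <- match.arg(variant)
  stopifnot(scoreThreshold > 0, scoreThreshold < 1,
            maskCutoff > 0, maskCutoff <= 1, minPixels >= 0)
  cfg <- list(variant = variant, scoreThreshold = scoreThreshold,
              maskBandNm = maskBandNm, maskCutoff = maskCutoff,
              fruitThreshold = fruitThreshold,
              minPixels = as.integer(minPixels),
              spectraPerClass = as.integer(spectraPerClass),
              maxK = as.integer(maxK), splitFraction = splitFraction,
              nTrainScenes = as.integer(nTrainScenes),
              nSound = as.integer(nSound),
              nCracked = as.integer(nCracked),
              samplingSeed = as.integer(samplingSeed),
              rmsevSeed = as.integer(rmsevSeed),
              splitSeed = as.integer(splitSeed),
              benchmarkSeed = as.integer(benchmarkSeed),
              phantom = phantom)
  class(cfg) <- "pipelineConfig"
  cfg
}

.variantClasses <- function(variant) {
  switch(variant,
         crack_vs_specular = list(positive = "CRACK",
                                  negative = "SPECULAR"),
         crack_vs_sound    = list(positive = "CRACK",
                                  negative = "SOUND"),
         stop("unknown model variant: ", variant))
}

.trainingRows <- function(bench, nTrainScenes) {
  m <- bench@manifest
  half <- nTrainScenes %/% 2L
  c(which(m$label == "SOUND")[seq_len(half)],
    which(m$label == "CRACKED")[seq_len(nTrainScenes - half)])
}

#' Harvest ROI spectra and train the pipeline's PLS-DA model
#'
#' Renders the benchmark's training scenes (first scenes of each class),
#' extracts ground-truth ROI spectra, samples `spectraPerClass` per
#' region, and fits the configured PLS-DA variant with RMSEV-selected
#' latent variables.
#'
#' @param bench a [PhantomBenchmark-class].
#' @param config a [pipelineConfig] list.
#' @param variant optional variant override.
#' @return A [PLSDAModel-class].
#' @export
trainModels <- function(bench, config = pipelineConfig(),
                        variant = NULL) {
  stopifnot(is(bench, "PhantomBenchmark"),
            inherits(config, "pipelineConfig"))
  variant <- variant %||% config$variant
  cls <- .variantClasses(variant)
  rows <- .trainingRows(bench, config$nTrainScenes)
  ## per-scene cap keeps the pooled matrix small; rare regions (crack)
  ## are kept in full
  cap <- max(250L, ceiling(config$spectraPerClass / length(rows)))
  pool <- NULL
  poolLab <- character(0)
  for (i in rows) {
    scene <- benchmarkScene(bench, i)
    ls <- extractSpectra(scene@cube, scene@truth)
    keep <- unlist(lapply(REGION_LEVELS, function(cl) {
      px <- which(ls@label == cl)
      if (length(px) <= cap) px
      else withr::with_seed(config$samplingSeed + i,
                            sample(px, cap))
    }))
    pool <- rbind(pool, ls@spectra[keep, , drop = FALSE])
    poolLab <- c(poolLab, as.character(ls@label[keep]))
    rm(scene, ls)
  }
  pooled <- LabeledSpectra(pool, poolLab,
                           seq(config$phantom$wlMin, config$phantom$wlMax,
                               length.out = config$phantom$bands))
  need <- c(cls$positive, cls$negative)
  sampled <- sampleSpectra(pooled, perClass = config$spectraPerClass,
                           seed = config$samplingSeed, classes = need)
  trainPLSDA(sampled, positive = cls$positive, negative = cls$negative,
             maxK = config$maxK, splitSeed = config$rmsevSeed)
}

#' Detect the stem-scar/crack region and measure its shape
#'
#' The study's image-processing chain: PLS-DA score image, binarization
#' at 0.5, 30% reflectance mask at 1098 nm, hole filling, mask
#' combination (AND), and deletion of components under 20 pixels. The
#' surviving region is measured with [roundness] and
#' [differentialDistance].
#'
#' @param cube calibrated reflectance [HyperCube-class].
#' @param model fitted [PLSDAModel-class].
#' @param config a [pipelineConfig] list.
#' @param sampleId,label identity carried into the feature row.
#' @return list with elements `region` ([RegionImage-class]), `features`
#'   (one-row data.frame; R and D are NA, with a warning, if the final
#'   region is empty) and `scores` (the score matrix).
#' @export
detectCracks <- function(cube, model, config = pipelineConfig(),
                         sampleId = "sample", label = NA_character_) {
  stopifnot(is(cube, "HyperCube"), is(model, "PLSDAModel"),
            inherits(config, "pipelineConfig"))
  scores <- scoreImage(model, cube)
  bin <- binarizeScores(scores, config$scoreThreshold)
  dark <- reflectanceMask(cube, bandNm = config$maskBandNm,
                          cutoff = config$maskCutoff,
                          fruitThreshold = config$fruitThreshold)
  dark <- fillHoles(dark)
  comb <- combineMasks(bin, dark)
  region <- removeSmall(regionImage(comb), config$minPixels)
  if (!sum(region@mask)) {
    warning("empty final region for ", sampleId,
            "; features flagged NA")
    feats <- data.frame(sample_id = sampleId, label = label,
                        R = NA_real_, D = NA_real_,
                        stringsAsFactors = FALSE)
  } else {
    feats <- suppressWarnings(
      extractFeatures(region, sampleId, label))
  }
  list(region = region, features = feats, scores = scores)
}

#' Run the full benchmark: simulate, train, detect, classify
#'
#' Generates the phantom benchmark, trains the configured PLS-DA variant,
#' runs detection and shape measurement on every scene, splits the
#' feature table 75/25, and fits/evaluates both LDA and linear SVM.
#' Scenes with an empty final region are excluded from classification
#' with a warning (none occur at the default operating point).
#'
#' @param config a [pipelineConfig] list.
#' @param verbose print progress every 25 scenes.
#' @return list with elements `features` (data.frame incl. flagged rows),
#'   `lda`, `svm` ([ClassificationReport-class]), `ldaModel`, `svmModel`,
#'   `plsModel`, `split` (the calibration/validation tables) and `seeds`.
#' @export
runBenchmark <- function(config = pipelineConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  bench <- generateBenchmark(config$nSound, config$nCracked,
                             seed = config$benchmarkSeed,
                             config = asPhantomConfig(config$phantom))
  model <- trainModels(bench, config)
  n <- nrow(bench@manifest)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    scene <- benchmarkScene(bench, i)
    lab <- if (scene@label == "CRACKED") "CRACKED" else "SOUND"
    det <- detectCracks(scene@cube, model, config,
                        sampleId = bench@manifest$scene_id[i],
                        label = lab)
    feats[[i]] <- det$features
    rm(scene, det)
    if (verbose && i %% 25L == 0L)
      message("  detected ", i, "/", n, " scenes")
  }
  features <- do.call(rbind, feats)
  usable <- features[!is.na(features$R), , drop = FALSE]
  if (nrow(usable) < nrow(features))
    warning(nrow(features) - nrow(usable),
            " scene(s) excluded from classification (empty region)")
  split <- splitFeatures(usable, fraction = config$splitFraction,
                         seed = config$splitSeed)
  lda <- fitLDA(split$calibration)
  svm <- fitSVM(split$calibration)
  list(features = features,
       lda = evaluateModel(lda, split$calibration, split$validation),
       svm = evaluateModel(svm, split$calibration, split$validation),
       ldaModel = lda, svmModel = svm, plsModel = model, split = split,
       seeds = c(sampling = config$samplingSeed,
                 rmsev = config$rmsevSeed, split = config$splitSeed,
                 benchmark = config$benchmarkSeed))
}

## phantom sub-config may arrive as a bare list after serialization
asPhantomConfig <- function(x) {
  if (!inherits(x, "phantomConfig")) class(x) <- "phantomConfig"
  x
}

#' Specular false positives of the two PLS-DA variants
#'
#' Trains both model variants on the benchmark's training scenes and
#' counts ground-truth specular pixels that survive score binarization at
#' 0.5, summed over `nScenes` scenes. The crack-vs-sound variant leaves
#' the specular highlights in the binary image (the documented failure
#' mode); the crack-vs-specular variant suppresses them.
#'
#' @param config a [pipelineConfig] list.
#' @param nScenes scenes (taken alternately from both classes) to score.
#' @return list with per-variant counts, the count ratio
#'   (vs_sound / vs_specular) and the number of specular pixels scored.
#' @export
specularFalsePositives <- function(config = pipelineConfig(),
                                   nScenes = 20L) {
  bench <- generateBenchmark(config$nSound, config$nCracked,
                             seed = config$benchmarkSeed,
                             config = asPhantomConfig(config$phantom))
  mSpec <- trainModels(bench, config, variant = "crack_vs_specular")
  mSound <- trainModels(bench, config, variant = "crack_vs_sound")
  m <- bench@manifest
  rows <- c(rbind(which(m$label == "SOUND"), which(m$label == "CRACKED")))
  rows <- rows[seq_len(min(nScenes, length(rows)))]
  counts <- c(crack_vs_sound = 0, crack_vs_specular = 0)
  nSpecPx <- 0L
  for (i in rows) {
    scene <- benchmarkScene(bench, i)
    spec <- scene@truth == 4L
    nSpecPx <- nSpecPx + sum(spec)
    counts["crack_vs_sound"] <- counts["crack_vs_sound"] +
      sum(binarizeScores(scoreImage(mSound, scene@cube),
                         config$scoreThreshold)[spec])
    counts["crack_vs_specular"] <- counts["crack_vs_specular"] +
      sum(binarizeScores(scoreImage(mSpec, scene@cube),
                         config$scoreThreshold)[spec])
    rm(scene)
  }
  list(counts = counts,
       ratio = (counts[["crack_vs_sound"]] + 1) /
               (counts[["crack_vs_specular"]] + 1),
       specularPixels = nSpecPx)
}
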