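# Reduced-size phantom configuration for unit tests: same structure and
# noise model as the full-size default, ~1/3 spatial scale so a scene
# renders in well under a second.
smallPhantomConfig <- function(label = "SOUND", seed = 1L, ...) {
  base <- list(rows = 96L, cols = 128L, bands = 60L,
               fruitRadius = c(34, 40), fruitJitter = 4,
               scarRadius = c(9, 13), scarJitter = 3,
               scarLobeHeight = c(2, 4), scarSpanCap = 4,
               sutureLength = c(3, 6), sutureWidth = c(2, 3),
               crackLength = c(9, 14), crackSecondaryLength = c(2, 6),
               crackWidth = c(2, 3),
               specularRadius = c(4, 7),
               label = label, seed = seed)
  do.call(phantomConfig, utils::modifyList(base, list(...)))
}

smallPipelineConfig <- function(nSound = 8L, nCracked = 8L, ...) {
  pipelineConfig(nSound = nSound, nCracked = nCracked,
                 nTrainScenes = 4L, spectraPerClass = 300L,
                 phantom = smallPhantomConfig(), ...)
}

# uniform-value reflectance cube helper
uniformCube <- function(value, rows = 6L, cols = 7L,
                        wl = seq(1000, 1700, length.out = 12L)) {
  HyperCube(array(value, c(rows, cols, length(wl))), wl, "reflectance")
}
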