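Package: crackscan
Title: Hyperspectral NIR Detection of Cuticle Cracks on Tomatoes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects cuticle cracks radiating from the stem scar of tomatoes
    in near-infrared (1000-1700 nm) hyperspectral reflectance images. Provides
    ENVI cube input/output with white/dark reference calibration, pixel-wise
    PLS-DA scoring via NIPALS partial least squares with RMSEV-based latent
    variable selection, binary mask combination and morphological cleanup,
    stem-scar shape descriptors (roundness and differential distance), and
    LDA / linear SVM classification of sound versus cracked fruit. Includes a
    synthetic tomato-phantom scene generator with ground-truth region masks so
    the full pipeline is testable without imaging hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    withr,
    e1071,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mixOmics,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Classification, Regression, Software
RoxygenNote: 7.3.3
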