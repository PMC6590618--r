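Package: shapelength
Title: Shape-Number Contour Length Estimation for Digitized Biopolymer
    Backbones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the contour length of single biopolymer strands
    (such as DNA imaged by atomic force microscopy) from their digitized
    single-pixel-width skeleton backbones.  Provides image preprocessing
    (thresholding, island filtering, thinning and debranching), Freeman
    chain coding, a complete taxonomy of the 64 single-width 4-pixel
    segments into 12 local shape classes, and a shape-weighted length
    estimator whose per-shape correction coefficients are calibrated by
    least squares against simulated worm-like-chain contours of known
    length across pixel resolutions.  Classical baseline estimators
    (Freeman, Kulpa, corner-count, and the DNA correction-factor
    estimator) are included for comparison, together with a seeded 2D
    worm-like-chain simulator and rasterizer that emulates the
    calibration corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
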