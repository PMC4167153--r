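Package: leukofuse
Title: Soft Fusion of Multichannel Expert Classifiers for Leukocoria Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects leukocoria (an abnormal white pupillary reflex symptomatic of
    retinoblastoma and other ocular pathologies) in cropped eye photographs by fusing
    a bank of 27 per-channel expert classifiers with a Sugeno fuzzy integral under a
    g-lambda fuzzy measure. Implements DCT-based illumination-invariant preprocessing,
    Karhunen-Loeve feature extraction to two components, neural-network, support-vector
    and discriminant-analysis experts with a calibrated certainty function, rank-derived
    fuzzy densities, baseline combiners (average, weighted average, majority vote), a
    repeated stratified 10-fold cross-validation harness with sixteen performance
    metrics, Friedman and Nemenyi post-hoc comparison of combination methods, and a
    synthetic eye-image generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
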