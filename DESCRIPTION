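Package: cephcam
Title: Interpretable CNN Saliency Cartography for Cephalometric
    Retrognathia Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for studying mandibular retrognathia (Class II
    malocclusion) on lateral skull radiographs with an interpretable
    convolutional neural network. Provides synthetic cephalogram phantoms
    with planted ground truth, Steiner-style ANB/SNA/SNB labeling and
    severity binning, image standardization (resize, min-max
    normalization, Sobel filtering) with seeded augmentation, a small
    configurable CNN trained with Adam and stratified k-fold
    cross-validation, gradient-weighted class-activation saliency maps
    (with a gradient-free Score-CAM variant), population-level global
    activation maps stratified by severity, thresholded region-of-interest
    metrics (class score, hot surface), and a mixed two-way ANOVA report
    with Bonferroni post hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
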