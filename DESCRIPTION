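Package: villusnet
Title: Deep Learning Analysis of Duodenal Biopsy Images with Activation
    Traceback and Biomarker Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for three-class classification of duodenal
    biopsy tissue images (healthy control, celiac disease, environmental
    enteropathy). Provides slide tiling, training/test patch extraction with
    reflections and gamma colour augmentation, a compact four-layer
    convolutional network with patch, image and case level probability
    aggregation, case-preserving stratified cross-validation with aggregated
    confusion matrices and false-negative rates, highest-activation traceback
    from fourth-layer feature maps to source-pixel segments via receptive
    field arithmetic, per-filter class-activation Welch tests, and a
    lasso-based framework correlating noninvasive biomarkers with network
    activation patterns, including importance-guided feature elimination and
    nearest-activation segment reconstruction. A seeded synthetic-cohort
    generator emulates multi-site, multi-image cohorts with class-specific
    micro-texture and linearly linked biomarkers so the whole pipeline is
    testable without real slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    tiff,
    glmnet,
    Matrix,
    randomForest,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
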