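Package: hemorad
Title: Radiomic Signatures for Hematoma Expansion Prediction on Non-Contrast CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, leakage-safe pipeline for building and validating
    radiomic, visual-marker and clinical signatures of early hematoma expansion
    in spontaneous intracerebral hemorrhage from non-contrast head CT. Provides
    a synthetic cohort generator with planted, calibrated effect structure;
    deterministic image preprocessing (isotropic B-spline resampling, density
    re-segmentation, coiflet-1 wavelet and Laplacian-of-Gaussian filter banks);
    a 1,130-feature radiomic extractor (shape, first-order, and five
    texture-matrix families); segmentation-stability and collinearity feature
    screening; empirical-Bayes location/scale batch harmonization fit on the
    discovery cohort only; LASSO-regularized logistic signature fitting with
    stratified cross-validation; and DeLong-based evaluation with threshold
    metrics and rank correlation against functional outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    sva,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
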