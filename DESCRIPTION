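Package: lungmorph
Title: Neonatal Lung MRI Morphometry with Ensemble Segmentation and
    Severity Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of neonatal chest MRI: synthetic
    phantom generation with analytic ground truth, multi-rater 2D U-Net
    ensemble lung segmentation fused by pixelwise majority voting,
    three-dimensional lung reconstruction from anisotropic slice stacks,
    extraction of 78 named morphologic features (volumetric, intensity and
    surface), and nested cross-validated classification and regression of
    bronchopulmonary dysplasia severity from lung, patient and clinical
    feature groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    ranger,
    nnet,
    pROC,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
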