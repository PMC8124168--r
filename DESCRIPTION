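Package: lnradiomics
Title: Radiomic Prediction of Axillary Lymph Node Status from Breast DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end radiomics pipeline for predicting axillary lymph node
    involvement from 3D post-contrast breast MRI lesion volumes. Implements
    iterative convex-hull smoothing of segmentation masks with 26-connectivity
    merging, histogram first-order features, 3D grey-level co-occurrence matrix
    texture in 26 displacement directions, local binary patterns on three
    orthogonal planes (plain, uniform and rotation-invariant codings), encoding
    of clinical and histological covariates, wrapper feature selection by
    best-first search under nested cross-validation with a selection-frequency
    stability rule, and cost-sensitive random-forest classification evaluated
    by cross-validated ROC/AUC. Ships a seeded synthetic-cohort generator so
    the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
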