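Package: edemagrade
Title: Glioma Grading from Peritumoral-Edema Radiomics in Fused MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for classifying glioma grade
    (low- vs high-grade) from radiomic features of the peritumoral edema
    region. Implements Laplacian re-decomposition (LRD) fusion of multimodal
    MRI weights, fused-image quality metrics (entropy, STD, PSNR, SSIM), an
    851-feature radiomic extractor (shape, first-order and five texture-matrix
    families over the original image and eight stationary-wavelet sub-bands),
    a shadow-feature (Boruta-style) all-relevant selector driven by
    gradient-boosted-tree importances, and class-weighted stratified
    cross-validated classifier selection over a fixed model menu. Ships a
    synthetic brain-phantom generator emulating BraTS-style cohorts so the
    whole chain runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    xgboost,
    ranger,
    e1071,
    nnet,
    glmnet,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    rlang,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
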