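Package: plnmrad
Title: Biparametric MRI Radiomics for Pelvic Lymph Node Metastasis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for predicting pelvic lymph node metastasis
    (PLNM) in prostate cancer from biparametric MRI (T2-weighted imaging plus
    an apparent diffusion coefficient map). Implements 3D radiomic feature
    extraction over lesion and lymph-node volumes of interest (first-order,
    shape, and five gray-level texture families computed on the original image
    and a 19-image filter bank), a cross-tissue Pearson-correlation feature
    filter that retains primary-lesion features correlated with metastatic-node
    features, t-test and LASSO feature selection, SMOTE-rebalanced support
    vector machine modeling with repeated stratified cross-validation, and
    DeLong-based comparison of competing models. A synthetic-cohort generator
    produces phantom image volumes and paired feature tables with a planted
    lesion-node shared signature for testing and benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    e1071,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
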