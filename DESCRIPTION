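Package: radioimmune
Title: Intratumoral and Peritumoral CT Radiomics Biomarkers of Tumor Immune Context
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for evaluating the lymphoid and myeloid immune
    context of solid tumors from CT radiomics. From 3D image volumes and binary
    tumor masks it builds intratumoral and peritumoral (3 mm ring) regions,
    extracts a 584-feature radiomics inventory (shape, first-order, and
    gray-level texture matrices at three quantizations per region), constructs
    lymphoid and myeloid radiomics scores (LRS/MRS) through an mRMR ->
    collinearity pruning -> LASSO and SVM-RFE overlap -> logistic regression
    cascade with Youden-index dichotomization, classifies four radiomics immune
    subtypes, and evaluates associations with IHC immune scores, survival
    (Kaplan-Meier, Cox with Schoenfeld diagnostics, Harrell's C, nomogram
    points), immunotherapy response, and exact Shapley feature attribution.
    A synthetic phantom-cohort generator with latent lymphoid/myeloid context
    stands in for private clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    glmnet,
    e1071,
    survival,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
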