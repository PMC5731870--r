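Package: cd3radiomics
Title: MRI Texture Radiomics for Predicting CD3 T-Cell Infiltration in Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking 3D MRI tumor texture to CD3 T-cell
    infiltration status. Generates synthetic two-modality (T1 post-contrast and
    T2-FLAIR) phantom cohorts with known texture parameters, preprocesses
    volumes (NAWM intensity normalization, isotropic reslicing, gray-level
    quantization), extracts an 86-feature radiomic panel (histogram, gray-level
    co-occurrence, neighborhood gray-tone difference and gray-level size-zone
    features plus tumor volumetrics), screens features for robustness to
    geometric ROI perturbation via intraclass correlation, performs
    all-relevant shadow-feature selection against continuous CD3 z-scores,
    fits a genetic-programming symbolic-regression classifier of binary CD3
    infiltration status, and computes the full evaluation suite (ROC/AUC with
    stratified bootstrap confidence intervals, exact binomial confusion-matrix
    metrics, Spearman concordance, covariate-adjusted regression,
    Kruskal-Wallis balance tests, and bootstrap AUC comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    ranger,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
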