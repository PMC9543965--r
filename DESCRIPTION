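Package: fibrolens
Title: Synthetic Fibro-Inflammatory Biomarker Cohorts and Discriminant
    Views of Early Diabetic Heart Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates case-control and three-arm pre/post lifestyle-
    intervention cohorts of plasma fibro-inflammatory biomarkers and
    cardiovascular phenotypes from published per-group summary statistics,
    and provides the accompanying analysis pipeline: log10 biomarker
    handling with geometric back-transformation, z-standardisation,
    k-nearest-neighbour imputation, case-control comparisons with
    Bonferroni correction, change-score models for randomised-trial arms,
    a diabetes-remission classifier, principal component analysis via
    singular value decomposition with a best-fit plane, and a Fisher
    linear-discriminant plane with an orthogonalised healthy-anchor
    vertical axis and resubstitution classification accuracy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
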