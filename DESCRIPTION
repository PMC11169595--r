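Package: tlntcp
Title: Normal Tissue Complication Probability Modelling of Temporal Lobe
    Injury After Re-Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling radiation-induced temporal lobe injury after
    two courses of intensity-modulated radiotherapy for recurrent
    nasopharyngeal carcinoma. Converts voxel dose grids to equivalent dose in
    2 Gy fractions (EQD2) under the linear-quadratic model, accumulates two
    treatment courses voxel-wise with optional time-interval recovery
    weighting (linear, quadratic or exponential in the inter-course gap),
    extracts cumulative dose-volume histogram indices (Dmax, D0.5cc-D5cc),
    fits logistic dose-response (NTCP) models with Nagelkerke R-squared,
    inverts them to tolerance doses (TD5/TD50) with parametric-bootstrap
    intervals, and validates models by ROC/AUC with DeLong confidence
    intervals. A synthetic cohort generator produces paired dose grids, lobe
    masks, clinical covariates and outcomes from a configurable ground-truth
    NTCP so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    pROC,
    RNifti,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
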