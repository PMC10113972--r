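Package: contuvol
Title: Pulmonary Contusion Volumetry and Outcome Statistics from Chest CT
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies traumatic pulmonary contusion on chest computed
    tomography. Segments the lung field by Hounsfield-unit thresholding,
    separates functionally normal lung (-950 to -450 HU) from contused
    parenchyma, detects pneumothorax air pockets with a 3D smoothing
    filter, and reports the contusion-to-total-lung volume ratio with the
    20 percent moderate/severe cutoff. Ships a synthetic thoracic CT
    phantom generator with ground-truth label maps, a synthetic trauma
    cohort simulator calibrated to published group summaries, and the
    accompanying statistical battery: Welch t tests (raw data or summary
    statistics), Mann-Whitney U, chi-square and Fisher exact tests for
    2x2 tables, empirical and binormal ROC analysis with Youden-optimal
    thresholds, and age adjustment by linear-regression residuals.
    Reads and writes NIfTI-1 volumes and reads uncompressed little-endian
    DICOM CT series without external imaging dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
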