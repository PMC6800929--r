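Package: noduletex
Title: CT Texture Analysis of Solid Pulmonary Nodules
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seeded 3D region-growing segmentation of solid pulmonary
    nodules in chest CT, Hounsfield-unit density histograms of the
    segmented nodule volume, first-order texture statistics (mean,
    variance, skewness and excess kurtosis), peak/plateau histogram
    shape classification, and diagnostic evaluation (ROC/AUC, Youden
    cut-offs, confusion-table statistics, two-reader ICC).  Includes a
    calibrated synthetic CT phantom generator so the whole pipeline is
    testable without patient data, minimal DICOM series I/O, and
    volume-doubling-time assessment of nodule growth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
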