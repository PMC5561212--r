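Package: teratoscreen
Title: Morphometric Teratogen Screening with Micropatterned Stem-Cell Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for morphometry-based in vitro teratogen screening
    with geometrically confined human pluripotent stem-cell colonies. Extracts
    four radial morphological features (Area, Position, SD, CV) of the
    Brachyury-positive mesoendoderm ring from single-channel fluorescence
    images via Otsu segmentation, determines each compound's lowest disruption
    concentration (LDC) from replicate feature tables by per-dose t-tests with
    a breakpoint rule, fits four-parameter logistic viability curves to extract
    IC25 values, and classifies compounds as teratogens with a two-step
    decision rule comparing the LDC against cytotoxicity thresholds and a
    scaled plasma Cmax, including leave-one-out scale-factor optimization with
    ROC/AUC. Ships the 30-compound reference screen table and a synthetic-data
    generator (colony images, feature cohorts, viability curves) with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    minpack.lm,
    e1071,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
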