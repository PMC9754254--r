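Package: BiopsyQC
Title: AI-Assisted Daily Quality Control for Gastrointestinal Biopsy
    Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A patch-based whole-slide-image classification framework and
    post-analytic daily quality-control engine for gastrointestinal
    endoscopic biopsy histopathology. Slides are tiled into 256x256 patches
    with a persistent index/location database, classified at patch level
    into Malignant / Dysplasia / Negative-for-dysplasia, aggregated into a
    reconstructed confidence-map slide for slide-level classification, and
    rendered as red/blue heatmap overlays. A keyword rule engine classifies
    free-text pathologic diagnoses and routes specimens to organ-specific
    models; a concordance engine compares diagnosis-derived and AI-derived
    classes per slide, builds a discordance-first review worklist, and
    computes QC metrics (ternary accuracy, NPV, binary malignancy metrics).
    A deterministic synthetic-slide generator with routine slide/scan
    artifacts makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    nnet,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, QualityControl, Pathology
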