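Package: myelinGT
Title: Myelin Ground-Truth Extraction and Annotator Evaluation for
    Multi-Channel Fluorescence Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Headless workflow for building gold-standard myelin
    segmentations from multi-spectral fluorescent z-stacks. Detects
    candidate myelin by co-localization of oligodendrocyte and axonal
    membrane signal after cell-body removal, represents expert markings
    as thickness-carrying polyline vectors with an open JSON
    serialization, converts between binary masks and vectors
    (skeletonization, junction splitting, polyline simplification,
    distance-transform thickness estimation), merges and adjudicates
    multi-annotator markings into gold-standard masks, and scores
    annotators by pixel precision. Includes a seeded synthetic-stack
    generator with known ground truth so the whole pipeline is testable
    without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
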