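Package: cellcryst
Title: Detection and Evaluation of In Cellulo Protein Crystals in Bright-Field Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated identification of protein crystals grown inside
    living insect cells, imaged by bright-field microscopy. Provides a synthetic
    scene generator for two crystal morphologies (large rod-like crystals and
    small clustered crystals with hexagonal cross-section) with exact instance
    ground truth, polygon annotation input/output in the Labelme JSON dialect,
    a pixel- and object-level evaluation suite (precision, recall, F-measure,
    Jaccard index, object-count error and its normalized variant), a trainable
    instance-segmentation stage with warm-start, incremental and combined
    training protocols, and an experiment harness that runs the full training
    matrix and reports a strategy-by-strategy table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
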