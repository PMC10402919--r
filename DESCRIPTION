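Package: outgrowthr
Title: Quantification of 3D Spheroid Outgrowth from Multi-Channel
    Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated quantification of cell outgrowth from 3D
    spheroids imaged by multi-channel confocal fluorescence microscopy.
    Projects Z-stacks to 2D per channel, segments the cell-covered
    outgrowth region from the spheroid core with a trainable
    random-forest pixel classifier (or a deterministic threshold
    fallback), and computes the outgrowth-to-core area ratio,
    per-channel integrated densities with regional percentages, and
    counts of individual cells that migrated out of the core. Includes
    a synthetic spheroid image generator with pixel-exact ground truth
    for validation, and cohort-level aggregation into per-condition
    means and fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
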