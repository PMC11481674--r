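Package: cortiquant
Title: Quantification of Plasma-Membrane Association in Yeast Confocal Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for measuring plasma-membrane association of
    fluorescently tagged proteins in single transversal confocal sections of
    budding yeast. Converts cell label masks into curated elliptical ROIs,
    partitions each cell into whole-cell, plasma-membrane-band and interior
    compartments, computes per-cell PM/cytosol mean-intensity ratios, extracts
    normalized intensity profiles along the membrane contour with two-channel
    colocalization and cortical-puncta overlap statistics, and aggregates
    cells into biological replicates for one-way ANOVA with Tukey HSD after
    Shapiro-Wilk and Levene checks. Includes a synthetic-micrograph generator
    with per-cell ground truth so every pipeline stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    tiff,
    car,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
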