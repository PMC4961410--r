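Package: ctcgate
Title: Image Cytometry and Sequential Gating for Specific Circulating
    Tumor Cell Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A verifiable image-cytometry pipeline for circulating tumor
    cell (CTC) enumeration and PD-L1 biomarker evaluation. Multi-channel
    fluorescence tiles are stitched, background-subtracted, segmented on
    the nuclear stain and quantified into per-cell mean fluorescence
    intensities; events are then classified through sequential gates with
    thresholds derived by density-valley finding on a representative
    sample. The package quantifies how CD11b+ CD45-low myeloid cells that
    stain non-specifically for cytokeratin contaminate the standard
    pCK+CD45- CTC definition and skew PD-L1 readouts, and ships a seeded
    synthetic-data generator (event tables and rendered 16-bit image
    tiles with ground truth) so every stage is checked by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tiff,
    foreign,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
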