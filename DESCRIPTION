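Package: nanospot
Title: Single-Cell Secretion Quantification for Nanowell Membrane Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies protein secretion from single cells captured in
    nanowell arrays and imprinted onto antibody-capture membranes, as used
    to measure PSA secretion of individual circulating tumor cells. Provides
    a ground-truth-annotated synthetic assay generator (multi-channel chip
    scans, imprint/secretion membrane image pairs, calibration dilution
    tables, enumeration event tables), per-well intensity measurement and
    phenotype gating (calcein/PSMA/CD45), imprint-lattice detection and
    similarity-transform registration of membrane to chip coordinates,
    secretion-spot segmentation with area and roundness filtering,
    standard-curve calibration from dilution series to pg/um^2 surface
    density, per-cell pg conversion, marker-concordance statistics for
    CK/PSMA gated event tables, and per-patient subpopulation summaries of
    secreting and non-secreting PSMA+/PSMA- cells.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
biocViews: SingleCell, CellBiology, Proteomics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
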