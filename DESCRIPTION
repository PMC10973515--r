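Package: hypoxiaShift
Title: Hypoxia Signature Scoring and Cell-State Shift Analysis in Glioma
    Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a shared hypoxia-response gene signature from paired
    bulk differential-expression contrasts, scores single glioma cells for
    that signature with expression-binned control genes, calibrates a
    hypoxia classification threshold against a marker-positive cell
    fraction (VEGFA), assigns Neftel cellular states (MES/AC/OPC/NPC) by
    module-score argmax, and quantifies hypoxia-driven state shifts per
    patient stratified by IDH mutation status.  Includes a synthetic
    single-cell and bulk data generator with planted expression programs so
    the full pipeline is testable end to end, plus readers and writers for
    MatrixMarket triplets, GMT gene sets and delimited DEG tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    Seurat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
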