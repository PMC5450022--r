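Package: morphotrace
Title: Live-Cell Morphology Classification, Lineage Tracking and EMT
    Scoring for Fibroblast-to-Neuron Conversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying direct conversion of mouse embryonic
    fibroblasts (MEFs) into neuron-like cells from hourly live-cell
    time-lapse movies: rule-based classification of cells into
    neuron-like, shrunken and MEF-like morphologies from shape features
    (length-to-width ratio, neurite outgrowths, nucleus-to-cytosol
    ratio), nearest-neighbour frame linking with division detection and
    lineage-forest reconstruction, population kinetics (doubling times,
    per-class time courses, high- versus low-mitosis conversion events,
    grid-based cell sampling), signed EMT and metabolism signature
    scores on log2 expression changes, and a microarray meta-analysis
    workflow (replicate averaging, control normalisation, symbol-based
    merging, up-regulation fractions, strong-EMT stratification). A
    seeded synthetic-data generator produces label-image movies and
    expression compendia with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
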