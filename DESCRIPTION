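Package: hichier
Title: Hierarchical Reconstruction of High-Resolution 3D Chromosome
    Models from Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs three-dimensional chromosome models from
    intra-chromosomal Hi-C contact matrices with a hierarchical
    strategy: topologically associating domains (TADs) are modeled
    independently at high resolution, a whole-chromosome scaffold is
    built at domain resolution, the two scales are reconciled through a
    scaling-ratio estimator, and the assembled model is refined against
    all contacts with an outlier-tolerant Lorentzian distance-geometry
    objective. Includes Knight-Ruiz and ICE matrix balancing, an
    insulation-score domain caller, interaction-frequency to distance
    conversion with grid search of the conversion exponent, model
    evaluation metrics (distance correlations, multi-resolution
    consistency, FISH-style probe distances, A/B compartment PCA), and
    a synthetic contact-map simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    data.table,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
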