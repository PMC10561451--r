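Package: fociscreen
Title: Foci-Based High-Content Screening for DNA Double-Strand-Break Modulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for foci-based high-content screening of
    DNA double-strand-break (DSB) modulators in fluorescent-reporter
    cardiomyocytes. Provides a synthetic two-channel fluorescence microscopy
    generator with exact ground truth (dose-dependent 53BP1-type foci,
    expression heterogeneity, non-signaling cells, camera noise), classical
    nucleus segmentation with brightness-adaptive thresholding and watershed
    splitting, threshold-based per-cell foci counting (top-hat plus robust
    statistics), a trainable three-class single-cell phenotype classifier
    (foci-positive / foci-negative / non-signaling), and the screening
    statistics layer: percent foci-positive well summaries, robust percent of
    samples (RPS) plate normalization, replicate aggregation and hit ranking,
    four-parameter logistic dose-response (IC50) fitting, Mann-Whitney screen
    QC, and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    nnet,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
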