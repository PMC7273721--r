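Package: vcsort
Title: Simulation and Analysis of Photoactivation-Encoded Visual Cell
    Sorting Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled image-based genetic screening in which cells
    are marked by timed photoactivation of a convertible fluorescent
    protein (Dendra2) and recovered by FACS on the activated:unactivated
    ratio. Implements seeded simulators for an NNK site-saturation
    nuclear localization signal (NLS) variant library, four-level
    photoactivation sorting, two-channel nuclear images, and single-cell
    RNA-seq with a planted morphology-linked program; bin-sort scoring of
    variant localization (weighted-average raw scores, two-anchor
    normalization, replicate aggregation); an amino-acid-preference
    linear NLS predictor with proteome scanning and precision/recall
    threshold calibration; nuclear segmentation with dilate-and-subtract
    cytoplasm rings, N:C ratio and shape-factor measurement; and a
    negative-binomial differential expression test against a continuous
    lobulation score with hypergeometric gene-set over-representation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    MASS,
    Biostrings,
    EBImage,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, SingleCell, Sequencing, CellBiology, Visualization
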