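Package: deepshape
Title: Deep Recurrent-Graph Prediction of DNA Shape Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts thirteen DNA shape features (minor groove width,
    inter-base-pair and intra-base-pair helical parameters) and their
    fluctuations at single-nucleotide resolution for sequences of arbitrary
    length. The core model is a stack of recurrent graph ("shape") layers
    over a double-linked chain of nucleotide or dinucleotide nodes: each
    layer widens the receptive field by exactly one base pair, so the
    flanking-region influence on a prediction can be selected by layer.
    Includes the k-mer query-table predictor the layered model supersedes,
    diagnostics for flanking-sequence bias in query tables, a synthetic
    shape-data generator with a known flank-decay ground truth for
    end-to-end validation, and an L2-regularized multiple linear regression
    (nested 10-fold cross-validation) that predicts transcription-factor
    binding specificity from k-mer and shape features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
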