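Package: synergene
Title: Discovery of Synergistic Compound Pairs from Transcriptional
    Reversal of Gene Sets and Chemical Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for prioritising two-compound
    combinations against a disease from transcriptomic and chemical
    evidence.  Disease-dysregulated gene sets are identified by
    differential expression and over-representation analysis, filtered by
    random-walk-with-restart proximity to disease targets and pruned for
    redundancy with the overlap coefficient.  Reversal of each gene set by
    a compound is scored with a betweenness-weighted Gwet AC1 agreement
    index (wAC) between disease and sign-flipped treatment regulation
    labels.  Signature sets specific to disease drugs feed per-compound
    (PS) and per-pair (TCS) graded combination scores, and candidate pairs
    are re-ranked with fingerprint-based synergy regression models.
    Chou-Talalay median-effect modelling computes combination indices for
    experimental validation.  Synthetic-data generators with planted
    ground truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    nnet,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
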