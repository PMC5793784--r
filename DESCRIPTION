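Package: splicefid
Title: Splicing Fidelity Analysis from Splice-Junction Evidence
Version: 0.1.0
Authors@R: person("Maintainer", "Splicefid", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies splicing error frequency (SEF) of novel and cryptic
    splice junctions in budding-yeast-like transcriptomes from STAR-style
    splice-junction tables, contrasts fidelity between strains with Fisher's
    exact tests and Benjamini-Hochberg FDR control, extracts intron sequence
    features (PWM splice-site and branch-point scores, k-mer frequencies, a
    base-pair-maximization folding-energy proxy), and predicts SEF from those
    features with a built-in random-forest regressor under threefold
    cross-validation. Ships a synthetic-data generator that emulates a small
    yeast-like genome with planted ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
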