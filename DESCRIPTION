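Package: ribostall
Title: Conditional Dual-Head Modeling of Ribosome Stalling Under Amino
    Acid Deprivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts per-codon ribosome footprint profiles from coding
    sequences under control and amino-acid-deprivation conditions with a
    conditional double-headed sequence model (relative-attention
    transformer or bidirectional recurrent backbone), and interprets the
    fitted model with integrated-gradients codon attributions,
    peak/Significance-Window statistics, and counterfactual beam-search
    motif extraction with Fisher/Benjamini-Hochberg enrichment
    validation. Includes the full pre-processing pipeline (replicate
    merging, normalization, quality filters, coverage-sorted splits,
    likelihood-ratio selection), seed-ensemble pseudo-label imputation
    with retraining, and a synthetic ribosome-profiling generator with
    planted, recoverable stalling determinants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    Biostrings,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
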