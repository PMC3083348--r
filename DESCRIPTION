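Package: oglcnacr
Title: Prediction and Crosstalk Analysis of Protein O-GlcNAcylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for sequence-based analysis of protein O-GlcNAcylation,
    an O-linked attachment of beta-N-acetylglucosamine to Ser/Thr residues.
    Provides a support-vector-machine site predictor built on sparse (one-hot)
    encoding of fixed-length sequence windows with terminal padding, grouped
    cross-validated grid search, ROC/AUC evaluation, and calibration of raw
    decision scores into estimated-precision lower bounds and lift over the
    corpus base rate. Also implements Yin-Yang crosstalk classification of
    phospho-sites identical or adjacent to O-GlcNAc sites, transfer of known
    sites onto ortholog sequences through pairwise global alignment, and
    two-sample-logo position-specific residue enrichment, together with a
    seeded synthetic proteome generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    e1071,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
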