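Package: xenosig
Title: Cross-Species Transfer of Single-Cell Transcriptomic Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting a mouse single-cell transcriptomic signature
    onto human single-cell data. Implements per-cell quality control with
    published hepatocyte and stellate-cell thresholds, liver zonation
    assignment from marker genes, Wilcoxon differential-expression calling
    with Benjamini-Hochberg correction, gene set variation analysis (GSVA)
    scoring, two mouse-to-human gene conversion routes (homology-class table
    lookup and macrogene-weight cosine-similarity pairing trained with a
    zero-inflated negative binomial autoencoder), and a per-cell "Tom score"
    that ranks human cells by similarity to a mouse reference population.
    Includes a two-species synthetic data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
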