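Package: rareniche
Title: Spatial Niche Statistics for Rare Marker-Positive Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Permutation-based spatial neighborhood enrichment testing for
    rare marker-positive cells in spatial transcriptomics slides, with
    companion analyses: marker-restricted co-expression correlation,
    peak-to-gene assignment within a transcription start site window and
    acetylation-expression log fold-change concordance, differential
    expression threshold filtering with hypergeometric overlap testing,
    and delta-Cq / chromosome-conformation-capture normalization
    utilities. Includes a synthetic-data generator with planted ground
    truth so every stage is testable without external accessions, and a
    command-line interface for scripted runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
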