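Package: orphanevo
Title: Evidence-Based Classification of Taxonomically Restricted Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evidence-integration pipeline that classifies predicted
    taxonomically restricted ("orphan") genes as protein-coding,
    prediction artifacts/pseudogenes, or non-coding-RNA candidates.
    Evidence streams are RNA-seq expression thresholds with
    permutation-based saturation analysis, exact full-length peptide
    matches against the predicted proteome, and purifying-selection tests
    based on maximum-likelihood dN/dS estimation under the Goldman-Yang
    M0 codon model with likelihood-ratio tests against neutrality and
    false-discovery-rate control.  Homology clusters are built from a
    local-alignment similarity graph with Markov clustering and split
    into orthologous, paralogous, and intra-species lineage-pair
    datasets.  A fully seeded synthetic-data generator produces complete
    inputs (gene models, expression matrices, peptides, fixed-difference
    variant tables) with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
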