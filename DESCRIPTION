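Package: pepfusion
Title: Multi-Granularity Feature Fusion for Multi-Label Therapeutic
    Peptide Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies therapeutic peptides into 21 (configurable)
    functional classes from sequence alone, fusing three granularities of
    representation: an atomic branch that converts peptides to SMILES and
    encodes the token stream with a small transformer, an amino-acid branch
    combining learned embeddings, multi-head self-attention and multi-width
    text convolutions over the residue sequence and its Chou-Fasman
    secondary-structure string, and a relational branch that builds a k-mer
    hypergraph over the corpus and extracts per-sequence features with a
    two-stage hypergraph attention network. Branch features are concatenated
    and mapped through fully connected layers to independent sigmoid outputs,
    thresholded at 0.5. Includes the standard multi-label evaluation metrics
    (precision, coverage, accuracy, absolute true, absolute false), a
    label-bearing FASTA dialect, and a synthetic motif-based data generator
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
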