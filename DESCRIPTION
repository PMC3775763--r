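Package: scophylo
Title: Single-Copy Ortholog Phylogenomics from Transcriptome Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for transcriptome phylogenomics:
    read- and contig-level filtering and CDS extraction, all-vs-all protein
    similarity with H-score normalisation, constrained average-linkage
    clustering into gene families, selection of one-to-one single-copy
    orthologs, progressive protein alignment with codon back-translation,
    missing-data filtering and supermatrix concatenation, maximum-likelihood
    and parsimony tree inference with fast bootstrap support, a
    gene-subsampling topology-stability protocol, strict-clock Bayesian
    dating on 4-fold degenerate sites, and Nei-Gojobori Ks screening of
    paralogs for whole-genome duplications.  A seeded synthetic-data
    generator (species trees, gene birth-death families, codon sequences,
    degraded transcripts and reads) provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    igraph,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
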