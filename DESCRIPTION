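Package: unitome
Title: Transcriptome Annotation and Domain-Based Interactome Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-assembly toolkit for de novo transcriptome projects in
    non-model organisms. Computes assembly summary statistics (N50, mean
    length), predicts proteins by six-frame longest-ORF selection, quantifies
    expression as FPKM, calls differentially expressed genes between two
    single-sample conditions with a negative-binomial exact test, transfers
    functional annotation from tabular homology and domain searches, infers a
    protein-protein interaction network from domain-domain interactions,
    analyses its topology (degree distribution, power-law exponent,
    topological coefficient, betweenness), extracts Steiner-tree subnetworks
    around seed genes, and performs Fisher-exact term enrichment with
    Benjamini-Hochberg correction. Ships a seeded synthetic-data generator so
    every stage is testable without external downloads, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
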