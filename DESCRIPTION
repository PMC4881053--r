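Package: rgevo
Title: Evolutionary Dynamics of Plant Disease-Resistance Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for studying the evolution of plant
    disease-resistance (R-) genes across related genomes: iterative
    homology-based identification of NBS-LRR-type gene candidates, domain
    architecture classification (CC, TIR, NBS, LRR), tandem cluster and
    synteny mapping, gene-structure classification (pseudogenes, truncated
    models), four-fold-degenerate-site phylogenetics with neighbor joining
    under the Kimura two-parameter model, parsimony reconstruction of
    gene-family gains and losses, and Nei-Gojobori dN/dS selection scans
    with Jukes-Cantor correction. Ships a multi-species synthetic-genome
    simulator with full ground truth so every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    ape,
    igraph,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
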