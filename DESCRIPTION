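Package: KsScape
Title: Homology, Ka/Ks Estimation and Ks-Landscape Dating for Legume Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative molecular-evolution toolkit for small curated gene
    families across related genomes, built around the nitrogen-fixation gene
    complement of six legumes. Provides homolog discovery with BLAST-like
    seed-and-extend local search and reciprocal-best-hit orthology, codon-aware
    progressive alignment with complete-deletion gap handling, Nei-Gojobori
    (1986) synonymous/nonsynonymous rate estimation with Jukes-Cantor
    correction, neighbor-joining trees with codon bootstrap, ortholog /
    inparalog / outparalog classification with tandem detection, and Ks
    proportional landscapes with peak typing that date whole-genome
    duplication, speciation and ancient duplication events. A codon
    sequence-evolution simulator with known duplication histories makes every
    stage testable by recovery of simulated truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
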