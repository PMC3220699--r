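Package: phylomapr
Title: Phylogenomic Profile Maps, Orthology and Whole-Genome Identity for
    Bacterial Comparative Genomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of bacterial genomes built
    around phylogenetic profiling. Constructs thresholded bit-score
    profile matrices from all-vs-all protein homology searches, embeds
    proteins into a two-dimensional phylogenomic map by Spearman
    correlation of their profiles and detects density "mountains"
    (putative functional modules), and tests each mountain for gene
    ontology, host-association and taxonomic enrichment. Also provides
    reciprocal-best-hit ortholog calling with minLrap and identity
    thresholds, n-set Venn partitioning and include/exclude gene-class
    extraction, whole-genome identity metrics (fragment-based average
    nucleotide identity and tetranucleotide z-score correlation), genome
    feature statistics from GenBank flat files, and a synthetic-data
    generator with planted ground truth so every pipeline stage can be
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    igraph,
    MASS,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
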