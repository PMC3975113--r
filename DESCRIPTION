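Package: rlparch
Title: Genome Architecture of Leucine-Rich-Repeat Receptor-Like Protein
    Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies leucine-rich-repeat receptor-like protein (LRR-RLP)
    genes from protein sequences by domain-architecture rules, calls genomic
    clusters and super-clusters of receptor genes by distance chaining,
    collects vicinity-associated genes, classifies small proteins of unknown
    function (SPUFs) and measures their enrichment in receptor
    neighbourhoods, builds neighbor-joining trees from the conserved C3-D
    receptor domains and quantifies phylogeny/locus concordance, compares
    wounded versus non-wounded expression by fold change, and scans promoter
    pairs for shared conserved blocks.  Ships a seeded synthetic-genome
    generator that plants all ground-truth structures so every stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    mclust,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
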