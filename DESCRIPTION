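Package: polyivd
Title: Intra-Varietal Homolog Diversity Analysis for Polyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the genes of a polyploid (e.g. hexaploid wheat) genome
    into homolog types (inparalogs, dyads, triplets with collinearity-confirmed
    outparalogs, single-copy orthologs, singletons), quantifies sequence
    diversity within homolog families with a per-family nucleotide diversity
    statistic over gene regions (2 kb upstream, 5'UTR, CDS, 3'UTR), dates
    duplications with NG86 Ka/Ks, measures expression divergence (tissue
    specificity tau, coefficient-of-variation/fold-change calls, co-expression
    module splitting, Fisher term enrichment), and detects and compares
    expansion gene families across genomes. Includes a synthetic three-subgenome
    genome generator with known truth labels so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
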