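Package: azamine
Title: Mining Bacterial Genomes for Azasugar Biosynthesis Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for discovering putative azasugar
    biosynthesis gene clusters in bacteria. Implements local pairwise protein
    alignment with BLAST-like statistics, sequence similarity networks (SSNs)
    with threshold sweeps and genus labelling, genome-neighborhood colouring
    and family co-occurrence summaries, detection of the diagnostic
    aminotransferase/phosphatase/dehydrogenase three-gene cluster (3GC),
    degenerate consensus-motif screening of proteomes, and neighbor-joining
    gene-tree versus taxonomy-tree discordance analysis. A synthetic-genome
    simulator with full ground truth exercises the pipeline end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    ape,
    phangorn,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
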