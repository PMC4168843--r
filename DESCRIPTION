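Package: barcodegap
Title: Barcode Locus Evaluation by Genome Divergence Scans and Distance
    Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates candidate DNA barcode loci, with mitochondrial
    genomes of scleractinian corals as the motivating case. Scans a pair
    of aligned mitochondrial genomes with sliding-window Kimura
    2-parameter (K2P) divergence and ranks annotated coding regions by
    divergence; classifies all pairwise K2P distances among labeled
    barcode sequences into intraspecific, intrageneric and other strata
    and summarizes their distributions (the "barcode gap"); builds
    neighbor-joining trees from the distance matrices; and simulates
    region-structured genome pairs and multi-genus barcode sets under a
    K2P substitution model so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
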