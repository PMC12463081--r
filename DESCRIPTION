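Package: pcgloop
Title: Classification and Comparative Analysis of Polycomb H2Aub Chromatin
    Loops from Capture Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of capture Hi-C experiments targeting
    H2Aub-marked (Polycomb PRC1) regions. Provides in-silico DpnII
    restriction digestion and bait-fragment mapping, length-conditional
    capture probe design over peak regions, five-way classification of
    H2Aub loops (Both-loops, PcG hub and Pure only-H2Aub or
    H2Aub/H3K27me3 loops) with anchor-sharing hub detection, wild-type
    versus PRC1-mutant loop-fate and histone-modification-fate
    cross-classification with association testing, occupancy enrichment
    of chromatin marks at target regions against length-matched random
    regions, and linkage of loop classes to gene expression. A seeded
    synthetic-data generator with planted ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
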