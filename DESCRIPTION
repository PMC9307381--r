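Package: meripr
Title: MeRIP-Seq m6A Peak Analysis with Enrichment Scores, Metagene Profiles
    and Motif Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of MeRIP-Seq (m6A) experiments with an
    IP/input design in two conditions: enrichment-based peak calling,
    within-group intersection and between-group union merging, per-sample
    signal counting, E-score differential methylation calls, metagene
    peak-frequency profiles over mRNA regions and lncRNA bodies,
    functional-area annotation, IUPAC motif enrichment with site erasure,
    and Fisher's exact gene-set enrichment with Benjamini-Hochberg FDR.
    Includes a seeded simulator that generates genomes, annotations,
    coverage tracks and term maps with planted ground truth, and an
    end-to-end pipeline with a reproducible output manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
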