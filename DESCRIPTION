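Package: tpghallmarks
Title: Genomic Hallmarks of Translocation Partner Genes in Hematological Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical characterization of translocation partner genes (TPGs)
    in hematological cancer from a translocation breakpoint table and standard
    genomic tracks. Implements breakpoint-relative protein-domain retention and
    functional categorization, a permutation test with BH-FDR for domain-category
    co-occurrence in fusion proteins, Bernoulli-mixture clustering of fusion
    functional profiles with cross-validated model selection, promoter and
    3'-UTR regulatory-feature comparisons, Hi-C trans-contact pair-proximity
    permutation tests with k-means central/peripheral nuclear partitioning,
    LOESS-smoothed replication-timing early/late enrichment, and clinical
    rare-versus-frequent recurrence comparisons. A synthetic-data module
    generates all pipeline inputs with known planted structure so every stage
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
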