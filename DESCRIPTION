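Package: hseprom
Title: Heat-Shock Element Scanning and Inducible Promoter Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and characterising heat-inducible promoters
    in insect genomes. Extracts fixed-length upstream regions anchored at the
    translation start (ATG), scans them for the three 15-bp heat-shock-element
    (HSE) consensus geometries (tail-tail, head-head, step/gap) bound by
    heat-shock factor, clusters the matches and selects minimal promoter
    fragments harbouring most HSEs, and quantifies heat induction downstream:
    RT-qPCR fold change by the 2^-ddCt method with a reference gene, and
    protein-normalised luciferase reporter induction with two-group t-tests and
    one-way ANOVA followed by Tukey HSD with compact letter display. A
    synthetic-data generator produces ground-truth-labelled genomes, Ct tables
    and reporter tables so every pipeline stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
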