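Package: genarch
Title: Comparative Genome Architecture Analysis for Teleost Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative analysis of genome architecture across
    species: gene, exon and intron size inference from GFF3 annotations,
    repeat-element content summaries from RepeatMasker output, haploid
    genome size (C-value) statistics with order-level non-parametric
    comparisons, Spearman genome-size correlates, and BUSCO completeness
    arithmetic.  Ships a synthetic-data generator that emulates annotation,
    repeat and C-value inputs with known ground truth so every pipeline
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    BiocGenerics,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
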