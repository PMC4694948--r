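Package: promedip
Title: Promoter Methylome Inference from MeDIP Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers promoter DNA methylation from MeDIP/input log2-ratio
    promoter tiling-array probe tracks using a windowed one-sided
    Kolmogorov-Smirnov probe score, calls methylation peaks and gene-level
    promoter methylation with MaxTen intensity summaries and strand-aware
    positional classification, compares methylated-promoter sets across cell
    types and conditions (Venn cores, sharing matrices, loss/gain
    transitions), classifies cell-type-selective and differentially
    expressed genes from normalized log2 expression matrices, and identifies
    genes with concordant methylation and expression changes. A
    synthetic-data generator with planted ground truth makes every stage
    testable end-to-end; small calculators cover ChIP-qPCR percent-input
    enrichment and bisulfite clone-matrix summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
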