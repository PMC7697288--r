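Package: reprolegit
Title: Reprogramming Legitimacy Analysis of Transcriptional Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates how legitimately a cell-fate reprogramming experiment
    moves gene expression from a starting cell type toward a target cell type.
    From a gene-level RNA-seq count matrix it computes median-of-ratios
    normalized counts, all-replicate activity calls, per-gene contrast
    statistics with Benjamini-Hochberg false-discovery control, a partition of
    any pathway gene set into sub-reprogramomes (up/down/shared/silent, with
    activatome and erasome flags), PIANO response categories (proper,
    insufficient, aberrant, and no reprogramming), scalar reprogramming
    quantification as summed log2 fold changes, and clustering-based
    assignment of reprogramming samples to reference cell types. A negative
    binomial simulator with planted ground truth makes every stage testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
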