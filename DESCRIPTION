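Package: lncpair
Title: Candidate lncRNA-mRNA Regulatory Interactions from Multi-Group RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers candidate long non-coding RNA (lncRNA) to mRNA regulatory
    interactions from multi-group RNA-seq expression data. Implements a
    five-step lncRNA filtration cascade (exon count, transcript length,
    overlap with annotated transcripts, expression level, coding potential),
    FPKM computation, negative-binomial Wald tests for differential
    expression with Benjamini-Hochberg adjustment, Pearson co-expression
    edges with t-distribution p-values, genomic co-localization edges with
    distance and orientation, their overlap within and intersection across
    group comparisons, hypergeometric gene-set enrichment, FASTQ read
    quality filtering, and Livak 2^-ddCt relative quantification. A
    synthetic-data generator emits annotations, count matrices and FASTQ
    fixtures with planted structure plus a truth ledger for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
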