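Package: edscope
Title: Discovery and Quantification of A-to-I RNA Editing from Matched DNA/RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for adenosine-to-inosine (A-to-I)
    RNA editing discovery from matched DNA and RNA sequencing. Implements
    per-position pileups with read-end trimming and base-quality filtering,
    matched-DNA genotyping to exclude genomic polymorphisms, a candidate filter
    cascade (multi-allelic, homopolymer, heterogeneous-cluster and
    isolated-site removal within a configurable window), rescue of heavily
    hyper-edited reads by seed alignment in an A-to-G-masked sequence space,
    per-repeat-family and global editing indexes, strand-aware recoding
    (amino-acid-changing) site annotation with multi-sample consensus, ADAR
    nearest-neighbor motif profiling, and noise estimation. Ships a synthetic
    read simulator with planted SNPs, editing clusters, recoding sites and
    hyper-edited molecules, providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
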