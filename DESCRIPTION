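Package: lncscreen
Title: Identification and Classification of Stress-Responsive Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable, fully tested re-implementation of a drought-responsive
    long non-coding RNA (lncRNA) identification cascade for plant
    transcriptomes: RPKM quantification with a 2-fold / FDR differential
    expression screen, an ORF-based non-coding filter with a pluggable
    coding-potential stage, positional classification of lncRNAs against a
    genome annotation (intergenic, intragenic, antisense, overlapping),
    hierarchical small-RNA precursor classification by exact-match read
    mapping and Smith-Waterman local alignment against miRNA precursor
    libraries, antisense lncRNA-CDS pairing, tissue-specificity scoring
    (tau index), and Pfaffl relative quantification for RT-qPCR validation.
    Includes a seeded synthetic data generator that plants ground-truth
    labels for every pipeline stage so the whole cascade is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
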