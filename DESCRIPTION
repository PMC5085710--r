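Package: budmiR
Title: Small RNA-Seq miRNA Discovery, Differential Expression and
    Degradome-Supported Target Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for two-library plant small
    RNA-seq studies: adapter trimming and tag collapsing, annotation-category
    partitioning against user-supplied reference sets, conserved miRNA
    identification by exact match to a mature reference, novel miRNA
    prediction from genome-mapped tags via hairpin excision, folding and a
    five-criterion duplex test (miRNA* support, duplex mismatches, 2-nt 3'
    overhangs, bulge limits, MFEI), Audic-Claverie differential expression
    with reads-per-million normalization and fold-change classes, rule-based
    complementarity target prediction, and degradome (PARE) t-plot cleavage
    site calling with permutation p-values. Ships a seeded synthetic-data
    generator with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
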