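Package: vcfjoint
Title: Joint Alignment-Based Benchmarking of Phased SNP, INDEL and SV Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-based comparison of a phased query VCF against a phased
    truth VCF that evaluates single-nucleotide polymorphisms, small
    insertions/deletions and structural variants jointly rather than per size
    class. Variants are grouped into clusters by cost-budgeted alignment
    reaches, truth and query clusters are merged into superclusters, and each
    supercluster is evaluated by reconstructing and aligning haplotype
    sequences, so that equivalent variant representations (a large deletion
    written as several smaller ones, indels shifted within tandem repeats)
    are credited as matches. Per-variant decisions (TP/FP/FN) carry a
    credit score in [0,1] with a configurable threshold. Phasing is evaluated
    on the same alignments: phase blocks from FORMAT:PS, switch and flip
    errors minimised by dynamic programming, and NG50-family contiguity
    metrics. Includes a seeded simulator of diploid references and
    truth/query VCF pairs with controlled representation divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
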