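Package: svtarget
Title: Small Vault RNA Target Prediction and Fragment Analysis
Version: 0.1.0
Authors@R:
    person("svtarget", "developers", email = "svtarget@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for identifying targets of small vault RNA
    (svtRNA) fragments. Provides Dicer-dependent fragment calling from
    small-RNA coverage profiles, a seed-constrained, wobble-aware duplex
    aligner with free-energy thresholding and target-loop architecture
    classification, shuffled/swapped-guide null controls, intron/exon/UTR
    feature annotation with length-normalised percentages and metagene
    profiles, and gene-set overlap enrichment statistics (representation
    factor, hypergeometric tail, permutation null). A synthetic-data module
    generates transcriptomes with planted binding sites, small-RNA read
    pileups and overlapping gene sets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
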