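Package: mircascade
Title: Three-Stage Machine-Learning Cascade for Ab Initio pre-miRNA
    Hairpin Prediction
Version: 0.1.0
Authors@R:
    person("Mircascade", "Developers", email = "mircascade@example.org",
           role = c("aut", "cre"))
Description: Completely ab initio prediction of microRNA precursor
    (pre-miRNA) hairpins from genomic sequence. A sliding window is folded
    through a triangular base-pairing matrix; candidate hairpins are
    assembled incrementally in three stages (exact stems, non-exact stems,
    complete hairpins) and each stage is gated by a random-forest
    classifier trained on SMOTE-rebalanced feature vectors. Includes
    stage-wise feature extraction (composition, pairing, loop/bulge
    geometry, energy indices, structure triplets), ARFF import/export,
    stratified cross-validation with in-fold SMOTE, sensitivity and
    selectivity evaluation against known hairpin annotations, and a
    synthetic-data generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
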