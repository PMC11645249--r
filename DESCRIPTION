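Package: exonstate
Title: Gene Structure Prediction with a CNN-biLSTM and a Differentiable
    Hidden Markov Model Layer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ab initio prediction of protein-coding gene structures in
    eukaryotic genomes. A convolutional and bidirectional LSTM network
    labels every base with one of 15 gene-structure classes (intergenic,
    three reading-frame intron states, and eleven reading-frame-aware
    coding-exon states including start, stop, donor and acceptor border
    states). A biologically constrained 15-state hidden Markov model with
    23 transition edges and a single emission-smoothing parameter turns the
    class probabilities into grammatical gene structures: differentiable
    forward-backward posteriors couple the HMM to the network during
    fine-tuning, and an exactly equivalent segment-parallel Viterbi decoder
    produces most-probable state paths at inference. Includes tiled
    two-strand whole-genome inference with second-pass boundary resolution
    and GTF output, a class-imbalance-aware CCE-F1 training loss, a
    synthetic-genome generator with planted gene structures for desk-scale
    experiments, and exon- and gene-level evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
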