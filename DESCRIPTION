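Package: exomotif
Title: Coverage-Weighted De Novo Motif Discovery from ChIP-exo Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: De novo discovery of transcription-factor binding motifs from
    ChIP-exo narrow peaks, weighting every sequence position by its
    normalized per-base sequencing coverage. Candidate sites are found by a
    two-stage all-against-all segment alignment scored with an upper-tail
    binomial statistic, assembled into motifs as disjoint maximal cliques of
    a segment-similarity graph, width-optimized by a binomial co-occurrence
    ("bookend") test that merges overlapping motif fragments, and refined by
    position weight matrix match-score expansion. Includes a restricted-range
    partial-AUC protocol for benchmarking discovered motifs against
    genome-sampled negative sequences, readers and writers for FASTA, BED,
    per-base coverage tracks, a combined coverage-FASTA format and MEME
    minimal motif output, and a seeded generator of synthetic peak sets with
    planted motifs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    igraph,
    optparse,
    pROC,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
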