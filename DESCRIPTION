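Package: polrate
Title: Transcription Elongation Rate Inference from Nascent RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Maintainer", "Polrate", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers RNA polymerase II transcription elongation rates from
    drug-block nascent-RNA sequencing experiments (Pro-seq/Gro-seq). A
    treatment library collected after a transcription-initiation block is
    compared against an untreated reference: the gene-body position where
    polymerase-depleted signal turns into intact signal is located with a
    two-stage least-sum-of-squares change-point scan over normalized
    treatment/reference coverage ratios, significance is assessed with
    one-sided rank-sum tests under multiple-testing correction, and the
    elongation rate follows from the depleted-region length and the block
    time. A two-state Gaussian hidden Markov model is provided as a
    baseline detector, together with assistant tools for pause indices,
    metagene profiles, GC content, k-mer enrichment and exon density, and
    a Poisson count simulator with an accuracy evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
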