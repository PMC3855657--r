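Package: tivscan
Title: Signal-Induced Transcript Isoform Variation from Exon-Array Time
    Courses and Scratch-Assay Screens
Version: 0.1.0
Authors@R: person("tivscan", "maintainers", email = "tivscan@example.org",
    role = c("aut", "cre"))
Description: Detects stimulus-induced transcript isoform variation (TIV)
    from exon-array-like probe-set signal time courses: intron-background
    based exon refinement, intensity-dependent noise modelling,
    FDR-controlled differential-expression and TIV event calling with an
    adjacency rule, and classification of events into the canonical
    alternative-transcript taxonomy (alternative first/last exons,
    cassette exons, alternative splice sites, intron retention). Also
    quantifies wound-healing scratch-assay image series into average
    migration distances and computes isoform-specific siRNA screen
    statistics. A synthetic-data generator provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
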