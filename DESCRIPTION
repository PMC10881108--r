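Package: cckit
Title: Peak Calling and Differential Analysis for Transposon Calling Cards Data
Version: 0.1.0
Authors@R:
    person("Calling Cards", "Toolkit Developers", email = "cckit@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of transposon Calling Cards data, in which
    a piggyBac transposase (optionally fused to a transcription factor)
    deposits transposons at TTAA tetranucleotides near binding sites. The
    package reads qbed insertion files, builds TTAA indexes from genome
    sequence, and calls peaks with three methods: a greedy gap-based caller
    (CCcaller), a sliding-window caller (MACCs), and a Bayesian-Blocks
    segmentation caller. Significance is assessed with a TTAA-density
    corrected Poisson model against a background insertion set or the local
    insertion rate. Downstream tools build cells-by-peaks and groups-by-peaks
    matrices, test differential binding with Fisher's exact or binomial
    tests, annotate peaks with their two nearest genes, pair differentially
    bound peaks with differentially expressed genes, intersect peaks with
    GWAS catalogs, compute signal-around-peak matrices, and refine yeast-style
    footprints with a two-component Gaussian mixture. A seeded simulator
    generates synthetic insertion data with known ground truth for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
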