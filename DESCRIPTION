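Package: satrep
Title: Satellite Repeat Enrichment, Chromocentre Counting and qPCR Quantification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pericentromeric satellite biology:
    builds per-family concatenated "repeat genomes" from RepeatMasker
    annotations (instances separated by an N spacer so reads cannot align
    across instance boundaries), counts ChIP-seq reads hitting each repeat
    family and computes input-normalised fold enrichment with confidence
    intervals, detects DRAQ5-bright chromocentre spots in single-nucleus
    images with an equivalent-radius filter and compares per-cell count
    distributions by a pooled chi-squared test, and performs ddCt relative
    expression, percent-input ChIP-qPCR and exponential decay fits. A
    synthetic-data module generates toy genomes, ChIP/input read sets,
    nucleus images and Ct tables with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    EBImage,
    methods,
    minpack.lm,
    Rcpp,
    Rsamtools,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
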