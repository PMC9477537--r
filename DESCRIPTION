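Package: peakshaper
Title: Multi-Scale Candidate Peak Detection and Wide-and-Deep Scoring for
    Genomic Coverage Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Peak calling for ChIP-seq, ATAC-seq and DNase-seq coverage
    tracks. A deterministic multi-scale detector builds a genome-wide
    enrichment map from 25 definitions of enrichment (five rolling-mean
    window sizes crossed with five fold thresholds over the chromosome
    mean) and extracts candidate peaks with size rules and recursive
    refinement. Candidates are scored by a wide-and-deep model: a small
    one-dimensional convolutional network reads a 2000-point signal window
    and returns a shape score, a logistic regression over 11 local
    enrichment measurements returns an enrichment score, and a multilayer
    perceptron combines both with the raw measurements into a single Peak
    Score interpretable as the probability that the signal arises from a
    biological event. Includes a synthetic coverage-track simulator with
    planted peaks and truth labels, an optional Poisson input-control test,
    labeled-region evaluation metrics, and a command-line interface with
    three operating modes (find-and-score, find-and-score with input
    control, and score-bed).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
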