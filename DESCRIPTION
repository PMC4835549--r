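Package: nanomapr
Title: Sensitive Mapping of Error-Prone Long Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-stage "read-funneling" mapper for long, error-prone
    sequencing reads such as those produced by nanopore instruments. Candidate
    locations are found with gapped spaced seeds that tolerate mismatches and
    1 bp indels, clustered by Hough-transform voting on the alignment-diagonal
    intercept, refined into exact-match anchors by a vertex-centric walk over a
    kmer mapping graph, chained with a variable-length LCSk dynamic programme,
    filtered with a 45-degree L1 regression, and finally aligned semi-globally
    (Myers bit-vector, Gotoh affine-gap, or anchored modes) with mapping
    quality and BLAST-like E-values reported in SAM output. The package also
    ships the synthetic-read generator (configurable mismatch/insertion/
    deletion profiles with per-base ground truth), and the evaluation suite:
    location and per-base precision/recall, majority-vote consensus calling,
    and window-vote structural-variant detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    Biostrings,
    IRanges,
    S4Vectors,
    optparse,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
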