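Package: dnakv
Title: Probe-Addressed Key-Value Storage in Synthetic DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Design and in-silico simulation of a key-value store on synthetic
    DNA. Generates large sets of mutually dissimilar microarray probes
    (barcodes) under biochemical constraints (GC content, homopolymer runs,
    hairpin avoidance, cross-similarity), using banded MinHash
    locality-sensitive hashing over k-mer sets to keep dissimilarity checks
    scalable. Encodes arbitrary byte payloads into constraint-satisfying DNA
    strands with a non-systematic fountain code (dense GF(256) random linear
    backend and a Luby-transform backend), anneals a probe key to each strand,
    and simulates microarray-based random access with error injection and full
    payload recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
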