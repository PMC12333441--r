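Package: delforge
Title: Design, Simulation and Decoding of Amide-Coupled DNA-Encoded Libraries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing three-cycle amide-coupled DNA-encoded
    libraries (DELs). Generates error-tolerant DNA codon sets (minimum pairwise
    Hamming distance 3, palindrome- and hairpin-free), enumerates the combinatorial
    library in silico (two N-Fmoc amino-acid couplings with Fmoc deprotection
    followed by a capping carboxylic acid, including truncate control wells),
    profiles lead-likeness descriptors, PCA diversity and principal-moments-of-
    inertia shape coordinates, simulates affinity selection against an immobilised
    target with bead-binding artefacts, pre-clearing, PCR and sequencing error, and
    decodes the resulting reads back to building-block counts with single-error
    barcode correction and per-cycle enrichment reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    cluster
Config/testthat/edition: 3
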