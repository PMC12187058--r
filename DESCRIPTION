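Package: dnarescue
Title: DNA Data Storage Decoding with Extra Low-Quality Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Encoder and decoder stack for fountain-coded DNA data storage
    that exploits low-quality sequencing reads usually discarded by standard
    pipelines. Implements an LT (Luby transform) outer code with a systematic
    (38,36) Reed-Solomon inner detection code over GF(2^8), biochemical
    constraint screening of designed oligonucleotides, a calibrated synthetic
    merged-read channel with distinct pass-filter and non-pass-filter error
    profiles, and a three-stage sequence-analysis workflow: exact clustering,
    edit-distance sphere clustering with center-star multiple alignment, and
    length-adjusted clustering of abnormal-length reads, each feeding a
    code-aided probabilistic majority-based (CAPMB) consensus and an iterative
    erasure decoder. Includes a random-sampling experiment driver measuring
    reading-cost reduction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
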