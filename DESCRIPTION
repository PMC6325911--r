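Package: oocmatrix
Title: Out-of-Core Eigendecomposition and Singular Value Decomposition for
    Large Genomic Relationship Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disk-backed ("out-of-core") factorization of dense matrices
    arising in statistical genomics. Computes full eigendecompositions of
    genomic relationship matrices (GRMs) and thin or top-k singular value
    decompositions of tall genotype matrices without holding the matrices,
    the factor outputs, or the solver workspace in main memory: large arrays
    live in memory-mapped files and are streamed through a bounded tile
    budget. Includes text/binary dense-matrix conversion, relative-norm
    verification metrics for comparing factorizations, a closed-form model
    of solver memory and disk footprints, seeded synthetic genotype and GRM
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
SystemRequirements: POSIX mmap (Linux, macOS)
OS_type: unix
Config/testthat/edition: 3
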