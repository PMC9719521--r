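Package: griffin
Title: Nucleosome Profiling of Cell-Free DNA with Fragment-Length-Specific GC Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles nucleosome protection and chromatin accessibility from
    cell-free DNA whole-genome sequencing, down to ultra-low-pass (0.1x)
    coverage. Implements a fragment-length-stratified GC-bias model
    (Benjamini-Speed fragment length position model) with k-nearest-neighbour
    median smoothing, GC-corrected composite fragment-midpoint coverage
    profiles around site lists (transcription factor binding sites, DNase I
    hypersensitive sites, differential ATAC-seq sites), three-feature
    quantification of accessibility (central coverage, mean coverage, FFT
    amplitude of the ~190 bp nucleosome periodicity), assessment statistics
    (tumor-fraction correlations, RMSE, MAD, signed-rank tests, ANCOVA), and
    bootstrap ridge-logistic classification with optional PCA reduction and
    patient-aware resampling for cancer detection and tumor subtyping. A
    synthetic cfDNA cohort simulator with analytic ground truth makes every
    stage testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    glmnet,
    jsonlite,
    rtracklayer,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
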