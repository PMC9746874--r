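Package: heartsc
Title: Combination Testing for Differential Expression in Sparse
    Single-Cell Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements HEART, a three-component combination test for
    differential expression between two groups of cells in sparse
    single-cell RNA-seq count matrices. Each gene is decomposed into an
    on/off state and the shape of its positive ("on") part; a pooled
    two-proportion z-test (detection rate), a Welch t-test (positive-part
    location) and a Brown-Forsythe test (positive-part scale) are combined
    with Fisher's method, with the chi-square degrees of freedom of the
    combined statistic calibrated genome-wide by maximum likelihood to
    account for dependence among the components. Also provides seeded
    benchmark generators (a splat-style gamma-Poisson simulator and a
    semi-simulation mechanism that swaps mean-matched gene pairs in one
    group of a real or synthetic matrix), confusion-matrix evaluation
    metrics, and readers/writers for 10x Genomics Matrix Market and
    delimited count formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
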