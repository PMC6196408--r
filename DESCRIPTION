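Package: tautcnv
Title: Taut-String Total-Variation Denoising for Read-Depth CNV Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects copy number variants (CNVs) from windowed read-depth data
    by denoising sample/normal log2-ratio signals with the taut-string solution
    of the 1-D total-variation problem, including Davies-Kovac local squeezing
    with a multiresolution residual criterion. Provides the surrounding
    pipeline: readcount outlier filtering, weighted-loess GC-bias correction,
    log2-ratio construction, circular binary segmentation, threshold-based CNV
    calling, moving-average and wavelet-shrinkage baseline denoisers, a
    benchmark simulator of piecewise-constant CNV signals with controlled
    signal-to-noise ratio, and segment-overlap evaluation metrics
    (sensitivity, false discovery rate, specificity, breakpoint accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
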