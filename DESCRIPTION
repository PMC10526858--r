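Package: neuroflux
Title: Calcium-Transient Detection, Network Synchrony and Single-Cell
    Differential Expression for Neuronal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for fluorescence calcium-imaging
    recordings of cultured neurons and for companion single-nucleus RNA-seq
    count matrices.  Detects calcium transients in per-ROI fluorescence
    traces with a threshold-and-rise-time criterion, quantifies network
    synchrony through the eigenvalue spectrum of zero-lag cross-correlation
    matrices of spike trains, compares experimental conditions with
    Kruskal-Wallis and Dunn post-hoc tests, and screens for per-cell-type
    differentially expressed genes with Wilcoxon rank-sum tests under
    Benjamini-Hochberg false-discovery control.  A ground-truthed synthetic
    data generator (Poisson spike trains with shared network events,
    indicator-kinetics trace rendering, disk-ROI movies, negative-binomial
    count matrices with planted fold changes) makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    tiff,
    EBImage,
    yaml,
    jsonlite,
    zoo
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr,
    optparse
Config/testthat/edition: 3
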