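Package: figseg
Title: Segmentation of Multi-Panel Biomedical Figures into Labeled Panels
    and Subcaptions
Version: 0.1.0
Authors@R:
    person("figseg", "maintainers", email = "figseg@example.org",
           role = c("aut", "cre"))
Description: Tools for splitting compound (multi-panel) biomedical figures
    into unimodal panels paired with their subcaptions. Includes harvesting of
    figure-caption pairs from a typed document operator stream, caption lexing
    with panel-label range expansion, recovery of panel labels from OCR tokens
    with a sequence-gap confidence heuristic, triangle-method histogram
    thresholding with 4-connected component extraction, panel-count estimation
    backed by a decision tree, minimum-cost layout-graph partitioning of the
    figure, and a synthetic fixture generator with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
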