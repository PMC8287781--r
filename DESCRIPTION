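Package: tempodeg
Title: Temporal Differential Expression Analysis for NanoString
    Neuroinflammation Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for NanoString nCounter panel count data
    from time-course injury studies: nSolver-style background thresholding
    and housekeeping geometric-mean normalization, two-group differential
    expression on log2 normalized counts with standard and conditional
    Benjamini-Hochberg false discovery rate control, classification of
    per-gene temporal differential-expression patterns and time points of
    peak change, categorization of treatment effects on gene trajectories
    (inhibited, induced, shortened, extended), pathway-level summaries,
    hypergeometric over-representation analysis on user-supplied gene sets,
    and a negative-binomial panel-count simulator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
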