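Package: netgba
Title: Differential Assessment of Gene Association Networks for Function
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the usefulness of one or more weighted gene-gene
    association networks for gene-function prediction. Baseline and subject
    network sets are each integrated into a composite graph by
    regression-based weighting, a guilt-by-association label-propagation
    classifier is cross-validated per function label (e.g. per GO term),
    and the per-label relative change (%ERR) in AUROC, AUPR and
    precision-at-10%-recall between the two rounds is reported as a sorted
    tab-delimited table. Includes a synthetic fixture generator with
    planted co-annotation signal and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    parallel,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
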