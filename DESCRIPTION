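Package: mlcps
Title: Cumulative Performance Scores for Classifier Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates a panel of classification evaluation metrics into a
    single cumulative performance score (CPS) by projecting the metric values
    as equally spaced rays on a two-dimensional polar plane and measuring the
    area of the closed polygon they enclose. Supports non-negative per-metric
    weights with zero-weight exclusion, whole-table scoring with a shared
    geometry, model ranking with a standard-deviation baseline, train/test
    rank-consistency reports, a standard binary-classification metric panel
    computed from labels and scores, synthetic classifier and metric-table
    generators for testing, and radar/bar/dual-axis visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
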