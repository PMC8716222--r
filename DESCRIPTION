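Package: mtlen
Title: Robust Elastic-Net Logistic Regression by Maximum Trimmed Likelihood
Version: 0.1.0
Authors@R: person("mtlen", "maintainers", email = "mtlen@example.org", role = c("aut", "cre"))
Description: Detects mislabeled samples in high-dimensional binary omics data
    by elastic-net penalized logistic regression based on trimming (MTL-EN).
    The trimmed subset is found either by the classic concentration step
    (C-step) over a regularization grid, or by the AR-Cstep algorithm, a
    concentration step hybridized with a Metropolis-type acceptance-rejection
    scheme that tolerates regularization parameters changing between
    iterations. Includes a reweighting step that flags outliers by Pearson
    residuals, outlier-detection and variable-selection accuracy metrics, a
    seeded generator of sparse logistic datasets with label-flip
    contamination, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
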