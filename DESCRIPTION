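Package: lgpsvm
Title: Hybrid Linear-Gaussian-Polynomial Kernel SVM for Microarray Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiclass soft-margin support vector machine built on a hybrid
    linear-Gaussian-polynomial (LGP) kernel, with particle swarm optimization
    of all kernel and penalty parameters, leakage-free per-fold principal
    component analysis inside 5-fold cross-validation, and imbalance-aware
    multiclass evaluation metrics (G-mean, macro F-score, weighted accuracy).
    Includes a synthetic generator for imbalanced, high-dimensional
    microarray-like expression data so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    kernlab,
    data.table,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
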