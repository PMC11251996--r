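Package: ratioqc
Title: Ratio-Based Quality Control for Multi-Batch Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality-control toolkit for multi-batch bulk RNA-seq built
    around profiling a set of related reference sample groups in every
    batch.  Implements ratio-based (relative-scale) expression profiling
    that cancels gene-wise additive batch effects, a PCA-weighted
    signal-to-noise ratio (SNR) metric with four diagnostic variants and a
    leave-one-out outlier diagnosis, construction of ratio-based reference
    datasets with homogeneity, stability and uncertainty budgets in the
    style of ISO Guide 35, and reference-dependent concordance metrics
    (relative correlation, RMSE, Matthews correlation of differential
    calls) with data-driven cutoff derivation and cross-validation.  A
    built-in synthetic multi-batch generator emulating the four-group,
    three-replicate reference design makes every component testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Rtsne
Config/testthat/edition: 3
RoxygenNote: 7.3.3
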