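Package: recumbency
Title: Automated Detection of Group Recumbency in Weaned Pigs from
    Camera-Derived Group Velocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting periods in which every pig in a pen is
    lying down (group recumbency) from the group velocity signal produced
    by an overhead camera tracking system. Provides a synthetic generator
    for tracked-position streams, ground-truth ethograms and images with
    controllable blur; cumulative group-velocity aggregation over 5-minute
    windows; Laplacian-variance blur quality control; two-observer binary
    behaviour coding with intercoder agreement and consensus labels;
    velocity-threshold classifiers (exhaustive accuracy-maximising search,
    a stepwise loop variant, and a mean-plus-SD rule); confusion-matrix
    metrics with 10-fold cross-validation; and an end-to-end pipeline
    with manifest outputs.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
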