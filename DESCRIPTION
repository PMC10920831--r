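Package: FeedScope
Title: Population Analysis of Calcium Imaging and Photometry During Feeding
    Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-cell calcium-imaging trace matrices and
    dual-channel fiber-photometry recordings collected while animals approach
    and consume food. Provides pose-based detection of approach and rearing
    epochs, variance-based cell inclusion filtering, peri-event alignment and
    pre/post eating modulation, isosbestic (405 nm) artifact correction,
    principal-component embedding of behavior-labeled population activity with
    silhouette and permutation-chance statistics, cross-assay cluster
    conservation via Mahalanobis and center distances over co-registered cells,
    matched-sample cross-validated behavior decoding with a temporal train/test
    gap, and onset-randomization bootstrap classification of behavior-modulated
    cells from Gaussian GLM coefficients. A synthetic-session generator with
    planted ground truth (behavior-modulated Poisson event trains convolved
    with a calcium kernel, pose tracks realizing the epoch schedule, and shared
    motion artifacts in photometry) makes every stage testable without raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    nnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
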