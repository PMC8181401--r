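Package: irgpairs
Title: Immune-Related Gene-Pair Prognostic Signatures from Within-Sample
    Expression Ranks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates prognostic signatures from immune-related
    gene pairs (IRGPs). A gene pair scores 1 in a sample when the first
    gene's expression exceeds the second's, so the resulting features depend
    only on within-sample ranks and transfer across platforms without
    normalization. The package covers the full workflow: probe collapsing
    and robust dispersion (MAD) filtering, exhaustive pair binarization with
    prevalence filtering, stability selection via resampled L1-penalized Cox
    regression, risk scoring with a published 22-pair head and neck squamous
    cell carcinoma signature shipped as a fixture, survival evaluation
    (Kaplan-Meier, log-rank, uni-/multivariate Cox, time-dependent ROC with
    Youden cutoff selection), non-negative least-squares immune-cell
    deconvolution with group-difference and correlation tests, and a
    synthetic-cohort generator that emulates multi-platform survival data
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival,
    glmnet,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
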