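Package: ctgpatch
Title: Patch-Based Transformer Classification of Antepartum Cardiotocography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying one-hour antepartum cardiotocography (CTG)
    windows as adverse versus normal pregnancy outcome with a patch-based,
    channel-independent transformer encoder. Includes a seeded synthetic CTG
    generator (fetal heart rate and uterine tone with accelerations,
    contraction-coupled decelerations and burst missingness), signal
    conditioning and fixed-length windowing, one-to-one propensity-score
    cohort matching with standardised-mean-difference audits, stratified
    train/validation splitting, network training with AUC-based early
    stopping and a pretrain/finetune protocol, a pluggable hyperparameter
    search harness, and ROC operating-point evaluation (default, Youden,
    high-sensitivity and high-specificity thresholds) with full metric
    panels and days-to-delivery sweeps. The transformer forward pass and
    its gradients are implemented in vectorised matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
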