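Package: mentalrep
Title: Mental Representation Structure and Motor Performance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studies of motor-memory structure and
    motor performance. Implements structural dimensional analysis of mental
    representation (SDA-M): scaling of binary splitting-task judgments into
    Euclidean distances between basic action concepts, unweighted
    average-linkage (UPGMA) dendrograms with a critical-value cut into flat
    cluster solutions, within/between invariance classification, and
    Hubert-Arabie Adjusted Rand Index comparison against a movement-phase
    reference partition. Also provides two-dimensional putting error scores
    (mean radial error, bivariate variable error), Holm-Bonferroni step-down
    contrasts with Cohen's d effect sizes, MIQ-R imagery scoring, and a
    synthetic-cohort generator emulating a four-group pre/post/retention
    mental-practice design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
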