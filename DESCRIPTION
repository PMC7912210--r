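Package: methdx
Title: Integrated Methylome-Transcriptome Biomarker Discovery for
    Case/Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-aware differential methylation and differential
    expression analysis for paired case/control methylome (Illumina
    450K-style beta values) and transcriptome (log2 intensity) cohorts,
    with integration into hypo-methylated/up-regulated and
    hyper-methylated/down-regulated candidate biomarker sets. Implements
    beta-value computation with an intensity offset, per-region and
    per-gene CpG aggregation, differential methylation calling by pooled
    decile delta-beta thresholds with a linear-model significance gate,
    dominant methylated region detection, an empirical-Bayes moderated
    t-test for differential expression, hypergeometric over-representation
    analysis against user-supplied gene-set collections, and random-forest
    classifiers evaluated by importance-ranked incremental feature
    addition under leave-one-out cross-validation with ROC/AUC summaries.
    A synthetic cohort generator with known planted truth makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
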