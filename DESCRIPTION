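Package: trainmark
Title: Trained-Immunity Biomarker Discovery from Multi-Cohort Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for prioritizing
    trained-immunity biomarkers from case/control bulk RNA-seq cohorts.
    Implements two-group differential expression with empirical-Bayes
    moderated t-statistics, weighted co-expression module detection via
    topological overlap and dynamic tree cutting, reference-signature
    immune-cell deconvolution with pseudocount ratio statistics and a
    subfunction correlation network, an ensemble machine-learning gene
    prioritization with permutation-importance fusion and principal-component
    extreme selection, cross-cohort ROC and random-effects meta-analytic
    validation, pre-ranked gene-set enrichment analysis, and single-cell
    high/low expression stratification. Ships a synthetic-data generator that
    emulates the statistical structure of the real cohorts so every stage is
    reproducible without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    pracma,
    glmnet,
    randomForest,
    e1071,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    limma,
    metafor,
    pROC,
    fgsea,
    mclust,
    jsonlite
Config/testthat/edition: 3
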