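Package: immunosig
Title: Immune-Stratified Prognostic Gene Panel Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for prognostic immune gene signatures in tumor
    cohorts. Stratifies patients by immune-cell infiltration profiles and by
    immune-regulatory gene expression using Gaussian mixture models, applies a
    cumulative standard-deviation cutoff to split long-tailed infiltration
    distributions into high and low groups, screens strata for survival
    association with Kaplan-Meier and log-rank statistics, ranks genes by an
    immune gene index (mean tumor expression times tumor/normal fold change),
    and builds multi-gene panels through differential expression, cell-type
    expression filtering, stepwise logistic selection, large-scale random
    combination AUC benchmarking against positive and negative control pools,
    frequency profiling, exhaustive subset search and leave-one-gene-out
    attribution. Includes a synthetic cohort generator with planted immune
    clusters, fold changes and survival effects so every stage can be tested
    against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
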