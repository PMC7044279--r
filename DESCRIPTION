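Package: SurvScreen
Title: Genome-Wide Survival Screening of Expression Biomarkers in AML Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for identifying candidate prognostic
    expression biomarkers in acute myeloid leukaemia cohorts. For every
    array probe, patients are min-max scaled and split into low (0-0.3)
    and high (0.7-1) expressers, the subgroups are compared on overall and
    event-free survival (Wilcoxon rank-sum, log-rank or Gehan-Wilcoxon
    tests with Kaplan-Meier summaries), covariate imbalance between the
    subgroups is detected with Fisher exact tests and removed by a seeded
    randomized shuffle, and the balanced groups are profiled with
    quantile normalization, empirical-Bayes moderated t differential
    expression, correlation-based hierarchical clustering and
    signal-to-noise GSEA with phenotype permutation. A fully
    parameterized synthetic-cohort generator with planted ground truth
    supports end-to-end testing without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    survival
biocViews: GeneExpression, Survival, DifferentialExpression, Microarray,
    GeneSetEnrichment, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
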