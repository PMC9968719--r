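Package: PhosphoStrat
Title: Phosphoproteomic Stratification and Drug Response Analytics for AML Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives phosphoproteomics signatures that stratify acute myeloid
    leukaemia cohorts (in particular KMT2A-rearranged cases) into biochemically
    distinct subgroups, and links the resulting groups to ex vivo drug response.
    Provides SummarizedExperiment-backed containers for log2 intensity omics
    layers, quality-control exclusion rules, missing-value-aware two-group
    t-statistics with fold-change counting rules and hypergeometric set
    enrichment, kinase-substrate enrichment analysis (KSEA) z-scores per sample
    or per contrast, signature derivation by t-test feature selection with PCA,
    hierarchical-cluster region definition and random-forest classification,
    four-parameter log-logistic dose-response fitting with drug sensitivity
    scores (DSS), proliferation-rate estimation, and Spearman correlation
    analyses between drug response and molecular features. A synthetic-cohort
    generator with planted subgroup, kinase and drug effects makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    mgcv,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, Classification, GeneSetEnrichment, Pharmacogenomics
RoxygenNote: 7.3.3
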