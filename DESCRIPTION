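Package: agenet
Title: Multi-Tissue Aging Transcriptome Analysis via Differential
    Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying aging biomarkers from
    multi-tissue bulk RNA-seq cohorts stratified into young and aging groups.
    Implements per-tissue two-group differential expression, condition-specific
    Spearman co-expression networks with edge-level false discovery rate
    control, a dysregulated-node statistic based on the change in positive-edge
    degree centrality between age groups with top-10 percent selection,
    cross-tissue Single/Some/Many categorization of differentially expressed
    genes and dysregulated nodes, integration of the two into a core biomarker
    set, and random-forest age-group classification with feature ranking and a
    composite multi-tissue predictor. Ships a negative-binomial cohort
    simulator with planted differential expression and planted co-expression
    modules so every stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
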