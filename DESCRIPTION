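Package: mirdcx
Title: Integrated miRNA-mRNA Differential Co-Expression Analysis for
    Two-Group qPCR Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrated microRNA and mRNA expression analysis in
    small two-group cohort studies profiled with TaqMan low-density qPCR
    arrays and expression microarrays. Implements cycle-threshold (CT)
    processing (detection filtering, delta-CT normalisation against an
    endogenous control, between-sample normalisation, signed fold changes,
    delta-delta-CT and efficiency-corrected Pfaffl quantification),
    SAM-style differential expression with permutation-estimated false
    discovery rates, permutation t-tests, Fisher linear discriminant
    classification with leave-one-out cross-validation, intersection of
    differentially expressed genes with microRNA target-prediction lists,
    a permutation test for group differences in miRNA-gene Pearson
    co-expression with four-way interaction classification and bipartite
    network export, clinical frequency tables with exact association
    tests, and a fully parameterised synthetic cohort generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
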