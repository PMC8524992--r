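Package: condep
Title: Conditional Dependency Analysis Across Cancer Cell Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A query layer and analysis toolkit for multi-omic cancer cell
    line panels in the DepMap/CCLE table style. Index tables unify gene and
    cell-line identifiers across CRISPR gene-effect (CERES) matrices,
    Bayes-factor essentiality matrices, RNA-seq counts, somatic mutation
    calls, protein localization annotations and protein-complex membership,
    so that cell lines can be stratified by lineage, disease, sex and
    mutation status and queried with conditional logic. On top of the query
    layer it implements four analysis procedures: stratified differential
    essentiality (mutual-information hypothesis reduction followed by
    per-gene Mann-Whitney tests with mean CERES differences and Cohen's d),
    a pan-cancer driver-mutation by essentiality chi-square screen with
    effect-size follow-up, negative-binomial Wald differential expression
    with median-of-ratios normalization and Benjamini-Hochberg correction,
    and confidence-scored plasma-membrane target nomination. A seeded
    generator of schema-compatible synthetic fixtures with planted signals
    makes every procedure testable without downloading any release data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
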