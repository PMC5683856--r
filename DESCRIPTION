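Package: biclustsig
Title: Bicluster-Derived Gene Signatures and Dose-Effect Enrichment for
    Toxicogenomics Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase workflow for deriving and applying gene signatures
    from multi-study transcriptomics compendia. The discovery phase binarizes
    gene-by-condition log2 fold-change matrices at a 2-fold threshold and
    enumerates inclusion-maximal all-ones biclusters (the Bimax model) in the
    up- and down-regulated matrices independently. The application phase
    scores the resulting gene sets for dose-effect enrichment in new exposure
    experiments: a one-way ANOVA F statistic for the dose effect is computed
    per gene, and a Welch two-sample t-test compares mean log2 F within a
    gene set to the mean over all measured genes. Includes a synthetic-data
    generator with planted biclusters and planted dose-responsive gene sets,
    median-based preprocessing (technical and biological replicate collapse,
    standardization to matched controls, multi-study merge on gene symbol),
    Spearman average-linkage ordering for heatmaps, TSV/GMT/JSON readers and
    writers, and a subcommand-style command-line interface.
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
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
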