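Package: methclock
Title: Epigenetic Age Prediction from Blood DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and applying epigenetic aging clocks from
    DNA methylation beta values in blood. Screens beta-value matrices for
    age-related CpG sites by Pearson correlation, fits multivariate linear
    age predictors with leave-one-out cross-validation, distils a minimal
    CpG signature by iterative train/test splits with recursive feature
    elimination and frequency ranking, and evaluates the published
    three-CpG pyrosequencing clock (ASPA, ITGA2B, PDE4C loci). Includes
    comparator analyses (telomere-length age regression, covariate
    association with age deviation, methylation entropy), a synthetic
    cohort generator for fully reproducible testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cli,
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
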