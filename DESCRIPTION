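Package: medegs
Title: Integrative Methylation-Expression Analysis for Methylation-Regulated Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for integrating genome-wide DNA methylation
    (450K-style beta values) with mRNA expression microarray data in a
    case-control design. Calls differentially expressed genes by covariate-
    adjusted linear models and differentially methylated positions by
    Wilcoxon rank-sum tests with a median delta-beta effect filter, annotates
    CpG probes by nearest transcription start site, gene-region category and
    CpG-island context, pairs the two layers per gene by maximum absolute
    Pearson correlation to classify methylation-regulated differentially
    expressed genes (MeDEGs), and searches for diagnostic gene panels with a
    radial-kernel support vector machine under leave-one-out cross-validation.
    Includes a synthetic paired-cohort generator that plants known
    differential signal and methylation-expression coupling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    e1071,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
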