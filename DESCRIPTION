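Package: reprogramome
Title: Transcription-Factor Reprogramome Classification for iPSC Reprogramming Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the human transcription-factor repertoire into cell-state
    categories (activatome, erasome, up- and down-reprogramome, equally active,
    inactive) from bulk RNA-seq counts of a start and a target cell type, calls
    early transcriptional responses to reprogramming-factor (OSKM) induction
    against dual reference conditions, and evaluates each response's
    reprogramming legitimacy (proper, insufficient, over, wrong, unwanted,
    irresponsive). Ships a self-contained negative-binomial differential
    expression engine (median-of-ratios normalization, method-of-moments
    dispersion, Wald test, Benjamini-Hochberg FDR), an escape hatch for
    externally computed differential-expression tables, and a seeded synthetic
    count generator with planted class labels for end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
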