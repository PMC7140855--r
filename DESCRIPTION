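Package: cellmatchr
Title: Match Tumor Transcriptomes to Cancer Cell Lines and Recommend Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a two-layer decision system for precision oncology:
    patient tumor transcriptomes are matched to their most similar cancer
    cell lines by Spearman rank correlation over the full shared gene set,
    and drugs are then recommended by averaging large-scale cell-line
    drug-screening AUC values across the matched lines and comparing them
    to per-drug sensitivity thresholds derived from a clinical
    response-rate knowledge base via a grouped-percentile rule. Includes
    accordance scoring against recorded clinical responses, Fisher's exact
    association tests, a cross-validated grid search for the number of
    matched cell lines, and a seeded synthetic-cohort generator with
    planted structure for end-to-end validation.
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
    withr
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
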