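Package: tftgenrich
Title: Transcription Factor Target-Gene Enrichment Analysis of
    Differential Chemotherapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription factors whose target programs respond
    differentially to chemotherapy across two cell phenotypes from a 2x2
    factorial expression experiment. Provides probe summarization and
    quantile normalization, per-gene factorial interaction modelling with
    rank-based selection of responsive genes, Fisher exact enrichment of
    transcription-factor target and pathway gene sets with odds ratios and
    multiple-testing correction, target versus non-target fold-change
    summaries with Welch tests, xenograft tumor-growth kinetics (volume,
    exponential growth rates, two-way interaction ANOVA), and a seeded
    synthetic-data generator with planted effects for end-to-end testing.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
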