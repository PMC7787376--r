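Package: vadsent
Title: Lexicon-Based Valence-Arousal-Dominance Sentiment Analysis of Short
    Survey Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring the emotional sentiment of short free-text
    survey responses with valence-arousal-dominance (VAD) word norms in the
    Warriner et al. format. Implements a word-to-lexicon matching cascade
    (exact, lemma, Porter stem, curated alias) with provenance accounting,
    per-respondent aggregation of three-word responses into activity-level
    VAD scores, descriptive word-frequency and word-overlap summaries,
    paired and independent comparisons with effect sizes, noncentral-t
    power analysis, hierarchical regression with semipartial correlations,
    fully-conditional-specification multiple imputation with Rubin's-rules
    pooling, and a seeded synthetic-cohort generator so every stage of the
    pipeline can be exercised and validated without access to raw study data.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
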