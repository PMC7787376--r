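# vadsent

Lexicon-based valence–arousal–dominance (VAD) sentiment analysis of short
free-text survey responses, built for the "three words" elicitation design:
respondents list three words describing how they feel about an emotionally
charged topic (here, death and dying) — once for themselves and once for how
they believe *others* feel at baseline, and again for themselves after an
intervention such as an online course.

Each word is scored on three crowd-rated norm dimensions on a 1–9 scale
(Warriner et al. format): **valence** (unhappy → happy), **arousal**
(calm → excited) and **dominance** (externally controlled → in control). A
respondent's score for an activity is the mean over their matched words,

```
V̄ᵢₐ = (1/nᵢₐ) Σ V(wᵢₐₖ),   k over matched words of respondent i in activity a
```

yielding nine analysis variables (3 activities × 3 dimensions). The package
implements the full measurement and inference chain:

* **Lexicon handling** — validated loading of any delimited VAD norms table,
  explicit per-dimension orientation flags with the `10 − x` scale reversal,
  exact lookup, and distribution summaries (`read_lexicon()`, `orient()`,
  `vad_lookup()`, `summarise_dimension()`).
* **Matching cascade** — normalisation (trim, lowercase, fuse hyphens and
  spaces, curated spelling map), then strictly ordered fallback resolution:
  exact match → dictionary lemma → Porter stem → curated alias → missing,
  with per-slot provenance accounting (`match_words()`, `match_table()`,
  `match_ledger()`). The Porter stemmer and dictionary lemmatiser are
  implemented in-package and injectable.
* **Scoring** — per-respondent activity means and the nine-variable
  respondent-level analysis table joined with socio-demographics
  (`score_activities()`, `build_analysis_table()`, `score_pipeline()`).
* **Descriptives** — word-frequency tables (occurrence counts with
  percent-of-respondents), unique-word counts, between-activity word-set
  overlap, and normalised score histograms for lexicon-vs-responses
  overlays (`top_words()`, `word_overlap()`, `score_histogram()`).
* **Inference** — paired t with d_z (d_z·√n = t), Welch/Student independent
  t with pooled-SD Cohen's d, Pearson correlations, Bonferroni adjustment
  with conventional truncated display, exact noncentral-t power analysis
  (`required_n_paired()`), and two-block hierarchical regression with ΔR²,
  ΔF and semipartial correlations (`hier_regression()`).
* **Multiple imputation** — fully-conditional-specification chained
  equations with proper Bayesian posterior draws (normal linear and
  logistic models), Rubin's-rules pooling with Barnard–Rubin degrees of
  freedom, pooled analyses over arbitrary estimators and min–max ranges for
  non-poolable fit statistics (`impute_fcs()`, `pool_estimates()`,
  `pooled_analysis()`, `fit_stat_range()`).
* **Synthetic cohorts** — a seeded generator with the study's demographic
  marginals, activity-level latent-VAD or multinomial word models,
  configurable attrition (MCAR or age-dependent) and missing-slot rates, so
  every stage is testable without the raw study data (`cohort_spec()`,
  `default_cohort_spec()`, `generate_cohort()`).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on every fitted object, and ggplot2 output
(`plot_radar()`, `autoplot()` on histograms).

## Worked example

```r
library(vadsent)

lex <- demo_lexicon()   # norms entries for common death-related words

resp <- tibble::tibble(
  respondent_id = rep(c("p01", "p02"), each = 9),
  activity = rep(rep(c("self_t1", "other_t1", "self_t2"), each = 3), 2),
  slot = rep(1:3, 6),
  word = c("sad", "Inevitable", "peace",  "fear", "scary", "sad",
           "peaceful", "natural", "peace",
           "dying", "sad", "natural",     "fear", "fear", "unknown",
           "peaceful", "peace", "")
)

out <- score_pipeline(resp, demographics = NULL, lex)
out$ledger
#>   provenance count   pct
#> 1 ORIGINAL      15 83.3
#> 2 LEMMA          1  5.56   ("dying" resolved to "die")
#> 3 STEM           0  0
#> 4 MANUAL         0  0
#> 5 MISSING        1  5.56   ("unknown" absent from this small lexicon)
#> 6 BLANK          1  5.56

out$analysis
#>   respondent_id self_t1_valence other_t1_valence self_t2_valence ...
#> 1 p01                      4.65             2.68            7.39
#> 2 p02                      3.40             2.93            7.88
```

The ledger partitions all 18 word slots by how they were resolved; the
analysis table holds the nine score variables. `4.65` is the mean valence of
p01's baseline words sad (2.10), inevitable (4.10) and peace (7.75) — words
about one's own feelings sit well below the scale midpoint, and the
course-end words score happier.

Paired contrasts of the activity profiles (here a toy n = 2, so nothing is
significant at the Bonferroni-adjusted level):

```r
compare_activities(out$analysis)
#>   comparison    dimension estimate statistic p.value cohen_d
#> 1 self_vs_other valence     1.22       1.62    0.352   1.15
#> 2 self_vs_other arousal    -1.15      -3.87    0.161  -2.74
#> ...
```

The a priori power analysis for a paired design at a very small effect:

```r
required_n_paired(d = 0.15, alpha = 0.0166, power = 0.95)
#> Paired-t power analysis: d = 0.150, alpha = .0166 (two-tailed), target 0.95
#>   required n = 729 (achieved power 0.9502)
```

For cohort-scale behaviour without study data, generate a synthetic cohort
whose generating activity means and demographics mirror the published study
conditions, then run the identical pipeline over it, with multiple
imputation for the course-end attrition:

```r
spec <- default_cohort_spec(n = 1350)       # 57% course-end attrition
lex9 <- lattice_lexicon()                   # dense synthetic vocabulary
coh  <- generate_cohort(spec, lex9, seed = 1)
at   <- build_analysis_table(coh$responses, coh$demographics, lex9)
mids <- impute_fcs(at, m = 20, maxit = 10, seed = 2,
                   vars = analysis_score_columns())
compare_activities(at, mode = "mi", mids = mids)
```

See the methods vignette (`vignettes/vad-sentiment-methods.Rmd`) for the
model, its assumptions and the design decisions.

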