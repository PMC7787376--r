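---
title: "Measuring affect toward death with VAD word norms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring affect toward death with VAD word norms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vadsent)
```

## The measurement model

The package measures the affect people attach to a topic from the words
they choose to describe it. Respondents provide exactly three free-text
words per elicitation activity: their own feelings at baseline
(`self_t1`), the feelings they attribute to others in the general public
(`other_t1`), and their own feelings again after an intervention
(`self_t2`). Each word is assigned three crowd-rated norms on a 1–9 scale
— valence, arousal and dominance, the three dimensions that classical
dimensional theories of emotion hold sufficient to span affective
responses — and a respondent's score for an activity on a dimension is
the arithmetic mean over their *matched* words. Three activities × three
dimensions gives nine respondent-level analysis variables; all inference
operates on these.

Two assumptions matter. First, word norms collected out of context are
taken to transfer to words produced in context — the usual working
assumption of lexicon-based sentiment measurement, and the reason the
elicitation asks for isolated words rather than sentences. Second, the
three dimensions are treated as separate outcomes, never summed into a
composite: their relationship is known to be non-linear, and they carry
distinct meaning (a word can be unhappy yet calm).

### Orientation

Rating instruments differ in which endpoint of the 1–9 scale is "happy"
or "excited". A lexicon therefore carries an explicit orientation flag
per dimension, declared at load time and never inferred from data; the
canonical in-memory orientation is *intuitive* (higher = happier, more
aroused, more in control), and `orient()` maps between orientations with
the reversal `x ↦ 10 − x`, the unique affine involution of [1, 9] that
swaps the endpoints. Declaring orientation in configuration rather than
guessing it from score distributions avoids silent sign flips, which
would invert every downstream contrast.

### The matching cascade

Free-text words frequently miss the lexicon (inflections, misspellings,
fused compounds). Resolution is a strictly ordered fallback cascade over
the normalised token:

1. exact lexicon lookup (`ORIGINAL`);
2. dictionary lemma (`LEMMA`) — inflected forms mapped back to a base
   form *that is itself a lexicon word*;
3. Porter stem (`STEM`) — suffix stripping, useful exactly when the stem
   happens to be a lexicon entry;
4. curated alias (`MANUAL`) — an explicit reviewer-supplied map,
   mirroring hand-correction after automated failure;
5. otherwise `MISSING`; blank slots are `BLANK`.

The first success wins, and later stages never override earlier ones: an
exact match cannot be displaced by an alias. Normalisation lowercases,
trims, strips surrounding punctuation and fuses internal spaces/hyphens
("pain-free" → "painfree", the form such responses take in word lists);
a curated spelling map — not an automatic spell-checker — handles known
misspellings, keeping the step fully reproducible and auditable. The
provenance ledger partitions every word slot into exactly one of the six
classes, so the match-rate table of a study is a direct export.

The lemmatiser and stemmer are injectable single-token functions. The
defaults are a dictionary lemmatiser driven by the target lexicon itself
(a candidate base form counts only if it is a lexicon word) and an
in-package implementation of the classic Porter algorithm. The cascade,
not any particular NLP toolkit, is the method.

### Scoring and partial responses

Per-dimension activity scores average the matched words only, with all
three dimensions using the same contributing set. By default a single
matched word suffices (`min_words = 1`); a strict `min_words = 3` mode is
available. Averaging available words rather than discarding partial
triples keeps partially responding participants in the analysis and hands
genuinely absent activities (attrition) to the imputation layer as `NA`.
Duplicate words within a triple are counted as given — a respondent who
repeats a word is weighting it.

## Inference layer

Within-subject contrasts (self vs perceived others; pre vs post) are
paired t-tests on complete pairs with the paired effect size
d_z = mean(diff)/sd(diff), so that d_z·√n = t exactly; between-group
contrasts default to Welch's unequal-variance test with pooled-SD
Cohen's d. With three dimensions per contrast family the significance
level is Bonferroni-adjusted to α/3, compared at full precision; the
conventional 4-decimal *truncated* display (".0166" for .05/3) is
cosmetic only. Zero-variance differences return a flagged degenerate
result instead of an error so multi-outcome pipelines stay total.

Power for the paired design is computed exactly from the noncentral t
distribution (df = n − 1, noncentrality d√n, two-tailed), iterating n
upward to the smallest value reaching the target. At d = .15,
level .0166 and 95% power this yields n = 729. A subtlety worth
recording: power software is conventionally fed the truncated level, and
.0166 gives 729 while the full-precision .05/3 gives 728; the package
computes either, and the acceptance machinery uses the truncated level
that the original a priori analysis states it used.

Socio-demographic moderation of change is modelled by two-block
hierarchical OLS: the course-end score on its baseline score (block 1),
then demographics (block 2), so block 2 coefficients describe predictors
of *change*. The block-2 increment is tested with the standard nested
ΔF, and each final-model predictor gets a semipartial correlation — the
signed square root of the R² drop when it alone is removed — which is
how "unique contribution to variance explained" is conventionally
reported in this literature.

## Multiple imputation

Course-end attrition is the dominant source of missingness in this
design (around 57% of baseline respondents). The package implements
fully-conditional-specification (chained-equations) imputation directly:
each incomplete variable is imputed in rotation from a conditional model
on all other modelled variables — Bayesian linear regression with proper
posterior draws (scaled inverse-χ² residual variance, normal
coefficients, fresh noise per cell) for continuous variables, logistic
regression with asymptotic-posterior coefficient draws for binaries. The
default is m = 20 imputations and 10 cycles each; chained equations on
tables like these typically mix within a handful of cycles, and the large
iteration caps some software exposes are solver limits, not burn-in
prescriptions. The seed is a required argument; there is no hidden state,
and a run is bit-reproducible.

Downstream estimates are pooled by Rubin's rules (estimate = mean;
T = W + (1 + 1/m)B; Barnard–Rubin degrees of freedom when a
complete-data df is supplied). Quantities with no within-imputation
variance attached — R², F and their increments — are not poolable and are
reported as min–max ranges across the completed datasets, the standard
presentation. A complete-case mode shares the entire downstream code
path, which is what makes the sensitivity comparison (complete-case vs
MI) a one-argument switch; with no missing data the two modes agree
exactly and all ranges collapse to points. By default every
numeric/logical column of the analysis table enters the imputation model;
the variable set is configurable (`vars`), since score-only imputation is
a defensible alternative.

## The synthetic cohort generator

The generator exists so that every pipeline stage — matching, scoring,
descriptives, inference, imputation — can be validated end-to-end without
the study's raw data. Its defaults are the published study conditions:
1,350 baseline respondents; age 49.5 (SD 12, truncated to 18–84); 93.7%
female, 87.7% Australia-resident, 71.1% health professionals, 68.5%
university-educated; activity-level VAD means self-baseline
(5.25, 4.33, 5.16), others-baseline (3.56, 4.82, 4.12), self course-end
(5.90, 4.19, 5.63); 57% attrition before the course-end activity.

Two word models are provided because neither frequencies nor means alone
pin down a generator:

* **Latent-VAD model (default).** Each (respondent, activity) draws a
  latent point from a trivariate normal around the activity mean; the
  three words are then drawn from a vocabulary with probability decaying
  as a Gaussian kernel in VAD distance from the latent point. Marginal
  latent SDs default to (1.3, 0.6, 0.95) — the respondent-level spreads
  implied by the published standard errors at the study's n — and a
  configurable share of the latent variance (default 0.4) is a stable
  per-respondent trait common to all of that respondent's activities,
  which is what makes baseline scores predictive of course-end scores as
  a repeated-measures design requires. The recommended sampling
  vocabulary is `lattice_lexicon()`, a regular 0.5-spaced lattice over
  the full 1–9 box: a lattice finer than the kernel width and wider than
  the latent distribution makes kernel-weighted draws near-unbiased for
  the latent point, so generated cohorts recover their generating means
  (the basis of the parameter-recovery tests).
* **Multinomial model.** Words drawn per activity from an explicit
  probability table; `word_probs_from_frequencies()` seeds one from a
  published top-20 frequency table, with residual mass spread over filler
  words.

Attrition is Bernoulli per respondent, either MCAR or MAR with dropout
log-odds decreasing in age (calibrated to the marginal rate); an optional
age-effect hook tilts the course-end valence/dominance gain linearly in
age to emulate moderation findings, off by default. A small
missing-slot rate (default 1%) emulates blank word slots.

What the generator does *not* emulate: real lexical choice (synthetic
vocabularies have no semantics, so frequency tables from latent-model
cohorts are meaningless), spelling errors, and any treatment mechanism —
the pre/post difference is injected through the activity means, not
modelled. Passing recovery tests therefore demonstrates that the pipeline
measures what its inputs contain, not that the substantive findings would
replicate.

## Numerical choices and degenerate inputs

* Duplicate lexicon words after normalisation are a hard error, not
  last-wins: lexicon integrity underlies every downstream number.
* A single-entry lexicon reports sd = 0 with a degeneracy warning,
  keeping summaries total.
* Paired tests with zero-variance differences return flagged degenerate
  results; both-groups-constant independent tests error.
* Regression designs are checked for aliasing (hard error) and minimum
  n; semipartial radicands are clamped at 0 against floating-point
  negatives.
* The imputation engine adds a tiny ridge (1e-5, scaled) to
  cross-product matrices for numerical stability, and pooling treats
  B = 0 (identical estimates) as the complete-data limit with normal
  reference.
* Top-k word tables break count ties alphabetically, for determinism.
* Histogram bins are left-closed with the top edge included, and each
  series is normalised to sum to 1 so differently sized word sets can be
  overlaid.

## Problem sizes used in validation

The shipped validation suite runs the full pipeline on synthetic cohorts
of n = 1,350 (the study size, MI with m = 20) and n = 2,000 (recovery of
the self-vs-others valence gap under MI), checks pre/post sign stability
across 100 seeded cohorts of n = 2,000, verifies the noncentral-t power
result against a 100,000-replication Monte-Carlo simulation, and checks
MI interval coverage under MAR missingness over 50 replications of
n = 250 — sizes chosen to hold Monte-Carlo error comfortably below the
tolerances being asserted.

## Known limitations

* Lexicon coverage bounds measurement: respondents' words absent from
  the norms are missing data, and the manual alias stage is a curated,
  not automated, remedy (ambiguous base forms must be left missing).
* Norms are ordinal 1–9 means treated as interval; distances near the
  scale ends are not guaranteed to mean what they do mid-scale.
* The imputation engine covers continuous and binary variables only —
  the types in the analysis table; unordered categoricals would need a
  multinomial conditional model.
* The generator's MAR attrition depends on age only; real attrition may
  depend on unobserved affect (MNAR), which neither the generator nor
  the imputation model represents.
* Part-of-speech-specific norms, non-English lexicons and
  sentence-level sentiment are out of scope.
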