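---
title: "Methods: from protection-profile text to explained prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from protection-profile text to explained prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohppfwa)
```

This vignette documents the models and procedures behind `ohppfwa`, the
assumptions they make, the parameters that matter, and the design
decisions taken where the methodology was genuinely open.

## The pipeline

Occupational Health Protection Profiles (OHPPs) are free-text restriction
sentences written by occupational physicians, each protecting one or more
of fourteen body parts at level MN ("must not use", more severe) or SN
("should not use"). The pipeline is: (1) normalize and parse the text into
a 28-flag profile (14 parts x 2 levels); (2) convert each appointment's
restrictions into per-part severity scores; (3) assemble records of
consecutive appointments; (4) regress weeks-to-next-appointment and
next-visit severities on those features; (5) explain predictions with
Shapley attributions; (6) summarise predicted severity by gender,
seniority and production area.

## Rule-based extraction

The extraction protocol is deliberately rule-based (keyword matching, no
learned components): the vocabulary is tiny, closed, and written by a
small set of authors, and every decision must be auditable by the
clinical team.

* **Normalization** lower-cases, strips non-word symbols (diacritics
  preserved — the source language is Portuguese), collapses whitespace;
  it is idempotent.
* **Level cues** (`must not` / `should not`, `não pode` / `não deve`) are
  searched at every position: profiles in the wild place the label at the
  end of the sentence as often as the beginning. Parts take the level of
  the nearest preceding cue, or the nearest following cue when none
  precedes (which handles end-of-sentence labels).
* **Fuzzy matching**: tokens of five or more characters match a keyword
  at edit distance at most 1; shorter tokens must match exactly. The
  bound absorbs single-character misspellings without letting short
  function words collide. The source method names the misspelling problem
  but no mechanism, so this bound is this package's own choice, and the
  lexicon (`inst/extdata/lexicon.yaml`) is an editable data file rather
  than code.
* **Laterality**: `left`/`right`/`both` markers within a short window
  around the part keyword, with markers *before* the part taking
  precedence so that coordinated phrases ("left wrist and left fingers")
  resolve correctly; `both X` and bare plurals expand to left + right.
  A sided part with no marker is flagged for review, never guessed.
* **Process-only restrictions** (vibration tools, manual material
  handling) legitimately carry no body part and produce an empty part
  list. A sentence with a cue but no recognizable content is returned
  with an `unparsed` marker — silent dropping would bias the scores.
* **MN precedence**: when one appointment tags the same part MN in one
  sentence and SN in another, the profile keeps MN only. Co-occurrence
  handling is unspecified in the source protocol; keeping the more severe
  protection is the conservative choice.

## Severity scoring

Scoring converts an appointment's restriction sentences into per-part
scores on a work-ability-index style 0-10 scale (categories: good 8-10,
poor 0-7; fractional totals strictly between 7 and 8 are rounded half-up
before classification). Each category c contributes a pool

    pool_c = (number of c-sentences naming at least one part) * w_c

with per-sentence weights w_MN = 1.0 and w_SN = 2.5. These weights are
anchored to the published worked example, whose pools print as 2 (two MN
sentences) and 5 (two SN sentences). The same source text opens with the
remark "SN = 1, MN = 0.5", which contradicts those pools; we treat that
remark as a severity-ratio aside and take the operative weights from the
printed arithmetic. Both readings are documented here because they cannot
be reconciled.

Three allocation modes divide the pools over parts:

* `sentence` (default): each category pool is split equally over that
  category's sentences, then over each sentence's parts. This conserves
  the pools exactly (sum of part scores = pool_MN + pool_SN) and treats
  both categories by one rule, which is why it is the default.
* `slot`: each sentence's share is the pool divided by the total number
  of part slots across the category's sentences, then split over that
  sentence's parts.
* `paper_compat`: MN by the sentence rule, SN by the slot rule. This
  mixed rule is the only combination that reproduces every printed cell
  of the published worked-example table (shoulders and fingers 0.5 each,
  trunk 5/3 printed as 1.66 after truncating at two decimals, wrists 5/6
  printed as 0.8 at one decimal). It is provided for fidelity without any
  claim about the original authors' intent; the published arithmetic is
  category-inconsistent, so a self-consistent default was required.

Scores are stored at full precision; the printed 1.66 and 0.8 arise only
at display time (truncation, respectively half-up rounding).

## Synthetic cohort generator

Real OHPP databases are confidential, so the generator is a first-class,
tested module that emulates the cohort structure the analysis assumes:

* **Demography**: female share 0.233; per-gender seniority from truncated
  normals (female mean 13.95, sd 7.78, range 4-27 years; male 18.62,
  8.33, 4-29); six production areas with fixed weights (Assembly 0.42,
  Body Construction 0.20, Paint 0.12, Quality Assurance 0.10, Metal
  Stamping 0.08, Special Projects 0.08 — plausible shares for a vehicle
  plant, chosen once).
* **Appointment counts**: truncated geometric (ratio 0.55) over
  {1..7, 9..12} with probability 0 at exactly 8, matching the reported
  histogram shape (monotone decreasing, a gap at 8).
* **Restrictions**: 1-4 body-part sentences per appointment over distinct
  regions (which keeps generated scores inside the published population
  envelope of roughly 0.19-5.33 per part), MN probability 0.5, both-sides
  probability 0.35, an 8% chance of an additional process-only sentence,
  and a persistence probability of 0.6 that a restricted region carries
  over to the next visit (making next-visit severity learnable).
* **Clerical noise**: five channels — level label moved to the end of the
  sentence (p = 0.10), per-token misspellings (p = 0.02), extra spaces
  (0.10), non-word symbols (0.10), capitalisation errors (0.10).
* **Interval model**: `weeks = max(min_interval, beta0 - sum(beta_p *
  score_p) + eps)`, `eps ~ N(0, sigma)`, with beta0 = 64 weeks (the
  baseline for an unrestricted worker, matching the reported base-value
  region), sigma = 2 weeks, min_interval = 1, and per-part effects in
  weeks per score unit with the dominant coefficient on the right
  shoulder (8; left shoulder and trunk 3; neck, elbows, wrists 2; the
  rest 1). The sign convention — higher severity, shorter interval — is
  what the attribution analysis is expected to recover.

Each channel (demography, restriction structure, text noise, intervals)
draws from its own seeded stream, so changing one channel's rates leaves
the other draws unchanged — this makes noise-robustness experiments
well-controlled and is tested.

What the generator does **not** emulate: the diversity of real clinical
phrasing (it renders from a small template set), correlations between
area/function and specific body parts, drift in physician style over
time, and genuinely non-linear interval structure. Passing tests
therefore demonstrate that the pipeline recovers what it assumes, not
that it would reach any particular accuracy on real profiles.

The reported cohort is ambiguous about whether "418 workers" are those
removed or retained when single-appointment workers are dropped; rather
than guessing, the corpus keeps all workers and `filter_multi_visit()`
exposes the modelling view.

## Features, splits and folds

One record per appointment with a successor; the interval target is whole
weeks (days / 7, rounded half-up — the source states "number of weeks"
without a rounding rule); a worker's final appointment is right-censored
and simply dropped, as in the original regression setup (no survival
model). Categorical attributes are encoded as stable integer codes from a
persistable vocabulary (the tree learners use ordinal splits; the
encoding scheme was unspecified in the source).

Splits and cross-validation folds are **worker-level**: the source is
silent, but record-level splitting would leak a worker's own history from
train to test, so group splitting is the defensible choice. Fold
assignment is longest-processing-time over shuffled workers, giving
near-equal record counts.

## The boosted-tree learner and metrics

The built-in learner is least-squares gradient boosting: start from the
target mean, then repeatedly fit a depth-limited regression tree to the
current residuals (exhaustive axis-aligned split search minimizing summed
squared error; ties break on the lowest feature index then smallest
threshold, so fitting is fully deterministic) and add its prediction
scaled by the learning rate. Defaults: 100 trees, depth 3, rate 0.1,
minimum leaf 5, no subsampling — fixed, documented values; hyperparameter
search is out of scope. Training MSE is provably non-increasing per
iteration at rate <= 1, which the tests assert, and with rate 1 and
sufficient depth the ensemble interpolates distinct training points.
External learners (rpart, randomForest, xgboost) plug into the same bench
behind one adapter interface and the bench runs with the built-in learner
alone; xgboost additionally serves as an independent cross-check of the
built-in implementation in the test suite.

Metrics: RMSLE (`sqrt(mean((log1p(pred) - log1p(obs))^2))`, a relative
error that scales down large outliers — asserted as an inequality against
raw-scale RMSE), R², MAE, and cross-validated R² over the worker-disjoint
folds. Negative predictions are clipped to zero before the logarithm,
with a warning (the source is silent on this case). Per-part severity
models are trained only on records where the part has a positive score
at the current or next visit, mirroring the per-part counts of the
published descriptives; parts with too little history are reported as
skipped rows rather than fitted on noise.

## Shapley attributions

The value function is **interventional**: `v(S)` is the mean prediction
over a background sample with the features in S taken from the explained
point. This is model-agnostic (any `predict` function works) and makes
the linear-model closed form and the axioms (dummy, symmetry, linearity,
efficiency) exact, all of which are tested. Exact mode enumerates all
`2^m` coalitions and is limited to m <= 15 features to bound time and
memory; beyond that, a permutation-sampling estimator (one background row
and one feature order per draw) is unbiased for the exact values, reports
per-feature standard errors, and distributes the small closure residual
proportionally to `|phi|` so the additive identity holds exactly in the
output. The base value is the background-mean prediction, which equals
the training-target mean only for calibrated models — a deliberate,
documented difference from using the raw target mean.

## Stratified severity shares

Within a stratum (gender; seniority bins 1-10, 10-20, >20 years with the
boundary values 10 and 20 in the upper bin; production area), each part's
share is 100 times its summed predicted severity over the stratum divided
by the total over all parts — non-negative, summing to 100. Shares are
computed from *predicted* next-visit severities by default (that is the
reporting convention being emulated), with an observed-scores switch for
diagnostics.

## Pipeline and CLI

`run_pipeline()` chains the stages deterministically per seed and writes
a manifest with per-stage row counts and file checksums; a stage failure
halts with the stage name while earlier artifacts are retained. The thin
command-line wrapper (`inst/scripts/ohpp.R`) maps subcommands onto the
exported functions; its `train` / `explain` / `report` subcommands
re-derive the worker split deterministically from the seed instead of
persisting fitted models, keeping every artifact on disk a plain text
table.

## Problem sizes used in the tests

The suite generates its own corpora: 25-60 workers for extraction
round-trips and the pipeline smoke run, 150 workers (about 160 records)
for bench fixtures, and 400 workers (400+ records) across five seeds for
the parameter-recovery study, where the planted right-shoulder effect is
recovered with test R² >= 0.7 and ranks first by mean absolute
attribution with the expected negative sign. Exact attributions are
verified on 12-feature models over 50 records with a 100-row background.
These sizes are the package's own choices, large enough for the
Monte-Carlo confidence intervals used in the calibration tests.

## Known limitations

* The lexicon covers the fourteen canonical parts in English and
  Portuguese; real corpora would need lexicon extensions (synonyms,
  abbreviations), which the data-file design anticipates.
* The extractor's laterality window is heuristic; pathological sentences
  (several regions with conflicting markers inside one window) can
  misattribute sides — such sentences are not produced by the generator
  and would need lexicon- or grammar-level handling.
* The scoring scale is a restriction-derived surrogate for the clinical
  work-ability index, not the questionnaire instrument itself.
* Intervals are modelled as uncensored regression targets; final
  appointments are dropped rather than treated by survival methods.
* `wai_category()` rejects totals above 10; profiles that accumulate
  more than four SN-weighted sentences can exceed the scale, in which
  case `score_profile()` reports the total with an `NA` category and a
  warning rather than silently capping.
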