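---
title: "Methods: wearable night-time physiology and diabetes screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable night-time physiology and diabetes screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wearadetect` screens for self-reported diabetes mellitus (DM) from the
signals a finger-worn wearable records during sleep. This vignette is the
package's own account of the science: the statistical model behind each
stage, the parameters that matter, what the synthetic cohort generator does
and does not emulate, and the numerical and design decisions taken where a
published feature description is ambiguous or proprietary.

## 1. The synthetic cohort generator

Real wearable cohorts of this kind cannot be redistributed, so the
generator is a first-class module: it produces subjects and per-night raw
streams with the statistical structure the downstream analysis assumes,
and every pipeline stage is developed and tested against it.

**Scalar summaries.** Nightly heart rate (`hr_average`, BPM), RMSSD (ms),
total sleep time (h) and diurnal temperature amplitude (deg C) are drawn
from class-conditional truncated normals whose default locations and
scales are the published cohort moments (DM vs no-DM-DX: HR 67.819/9.569
vs 62.713/8.852; RMSSD 30.141/17.180 vs 42.944/24.973; TST 7.649/1.990 vs
7.946/1.726; amplitude 6.008/2.438 vs 7.261/2.848). Only means and SDs are
published, so the family is a modelling choice; truncation keeps the
physically non-negative quantities non-negative (TST is floored at 2 h — a
shorter "night" would not be a night record). Each scalar is decomposed
into a subject-level trait and night-to-night jitter with an intraclass
correlation of 0.7, a typical value for nightly resting physiology; the
pooled nightly moments equal the configured ones either way, but the
decomposition is what makes multi-night windows informative beyond single
nights, and it sets the effective sample size of any cohort-level
Monte-Carlo estimate (the number of subjects, not nights — the package's
distribution-recovery tests therefore simulate many subjects with few
nights each).

The nominal between-class effect size implied by the defaults under the
pooled-SD formula is d = 0.554 for HR; the published nightly-level d of
0.607 is not reconstructible from the published moments under standard
pooled-SD formulas (it evaluates to roughly 0.55–0.58), so the generator
targets its own nominal d, and tests assert recovery of that quantity.

**Hypnograms.** Sleep bouts end with a per-30-s-epoch geometric hazard
(default 0.002 control, 0.006 DM — insomnia-like fragmentation is more
frequent in the DM class); wake bouts are mostly 0.5–10 min, with a
60–110 min "detachment" gap whose probability grows with the hazard, so
high-fragmentation nights can contain a main sleep span plus a detached
short span. Subjects vary log-normally (SD 0.5 on the log scale) around
their class hazard. Stages within sleep cycle through light/deep/REM runs
with geometric lengths (mean 10 min); stage identity matters only through
sleep-vs-wake for the feature set, plus the stage-specific RMSSD
passthrough among the scalars.

**Temperature.** Each 24-h day is anchored at local noon, so one sleep
episode sits wholly inside one day (no published convention exists; this
one avoids splitting nights across days). The minute series is a baseline
(33 deg C) plus a sinusoid of peak-to-trough height equal to that night's
amplitude draw, peaking at the sleep midpoint (distal temperature rises
during sleep), plus stationary AR(1) noise with marginal SD 0.35 deg C.
The AR coefficient is a subject-level draw (control location 0.55, DM
0.75, between-subject SD 0.20, truncated to [0, 0.95]): smoother noise in
the DM class encodes the reduced signal complexity associated with
autonomic dysfunction, while the between-subject spread keeps the classes
overlapping — a deterministic per-class coefficient would make complexity
an implausibly perfect separator.

**Cohort structure.** Five age bins (30–39 through 70–79) with
class-specific sampling weights mirroring the published cohort's shape,
sex M/F/O, and independent per-night Bernoulli missingness (default 0.35,
matching the published 60–66% data completeness over the 129-night span;
no informative-missingness model, since none is published). The default
date range 2020-04-22 to 2020-08-29 spans 130 inclusive calendar days; the
published denominator is 129 nights, so the final date is treated as
exclusive. Optionally a fraction of control subjects carries another
chronic condition: their sleep/HR trait locations are shifted a
configurable fraction (default 0.5) toward the DM locations while their
temperature parameters stay untouched — encoding the finding that
temperature features are what separates DM from other chronic conditions.

Determinism: one root seed spawns a child stream per subject, so a
subject's records do not depend on how many other subjects are simulated,
and identical configurations yield byte-identical output files.

**What the generator does not emulate.** No raw PPG, no circadian phase
shifts (shift work, travel), no menstrual or weekday/weekend cycles, no
seasonal drift, no informative missingness, no minute-level temperature
dropouts within present nights. Passing tests on synthetic data therefore
demonstrate that the pipeline recovers structure of the kind assumed, not
that the classifier's absolute performance transfers to real cohorts.

## 2. Sleep-window phenotyping

A night's hypnogram (30-s epochs in W/L/D/R between sleep onset and final
wake onset) is segmented into windows of contiguous sleep: long if the
span exceeds 6 h, short if under 3 h. The two published rules — internal
wake runs of at most 10 min, windows separated by at least 60 min of wake
— are contradictory for gaps of 10–60 min. The package resolves by the
separation rule: gaps shorter than 60 min merge into one window, with the
gap counted as the window's wake time; `strict = TRUE` instead splits at
any gap over 10 min. Both behaviours are exercised in tests. Spans of
3–6 h are `other` and counted in neither aggregate (the source material is
silent on them). Boundary conventions: a gap of exactly 60 min separates;
a gap of exactly 10 min does not split in strict mode. Leading and
trailing wake belongs to no window.

Aggregates follow: counts (`LW_count`, `SW_count`), summed sleep and wake
time per kind (`ST_*`, `WT_*`), and total span per kind (`LW_len`,
`SW_len`), each `NA` when that window kind did not occur. Taking the
literal reading of "sleep time divided by wake time" for sleep efficiency
yields a ratio, not a percentage; the default `sleep_percentage` is
sleep/(sleep+wake) over the sleep period, with
`sleep_percentage_mode = "ratio"` for the literal reading. Three primary
counters have no published definition (they are proprietary device
outputs), so the package computes documented surrogates: `restless` =
stage transitions into wake, `got_up_count` = wake runs of at least 5 min,
`wake_up_count` = interior wake runs; `onset_latency` is 0 by construction
in synthetic data. Onset arithmetic is circular on the 24-h dial
(`total_sleep_time` is the circular difference of the onsets,
`midpoint_time` the circular midpoint).

## 3. Temperature features

**Percentile filter.** Each 24-h day is filtered to its [5th, 95th]
percentile band — values *strictly* outside are removed, so a constant day
survives intact. Quantiles use linear interpolation between order
statistics (R type 7); no method is published, and the choice is recorded
here and asserted in tests (survivors of 1..100 are exactly 6..95). Days
with fewer than 20 observed minutes yield all-null temperature features
rather than unstable quantiles.

**Diurnal metrics.** Amplitude = max − min of surviving values;
`sleep_mean`/`wake_mean` average surviving minutes inside/outside the
circular sleep interval, with empty sets giving `NA` (and hence `NA`
difference).

**Complexity.** The complexity index of a series is the root-sum-square of
successive differences of the z-scored series divided by its length. Two
quantities are unstated in the source material and fixed here: the z-score
uses the population SD (divide by N), and the normalizing length is that
of the grained series being scored. A zero-variance series scores 0 by
convention; series shorter than 2 return `NA`. By construction the index
is invariant to affine rescaling, which is tested as a property. The
profile takes the 256 minutes centred on the night midpoint (128 either
side, midpoint from the onsets), requires them all observed and inside the
sleep interval — blocks are never shifted toward valid data, because the
onset-adjacent variance is exactly what the centring avoids — and
coarse-grains at dyadic scales s = 0..3 (block means of width 2^s,
trailing remainder dropped), giving series of lengths 256/128/64/32.

Two surrogates stand in for proprietary device outputs:
`temperature_deviation` = night mean minus the subject's trailing 30-night
baseline mean, and `temperature_trend_deviation` = that deviation minus
its trailing 3-night mean.

## 4. Windows, quality filters, splits

The 36 features are assembled by outer join on (subject, night); a night
with no extractable feature at all is absent, while a night missing one
input stream keeps its row with that block `NA`. Windows of length L in
{1, 3, 7, 14, 21} are extracted with a 1-night stride, but only at
*anchor* start dates: the start dates of 21-night windows in which no
aligned week (nights 1–7, 8–14, 15–21) has more than 2 missing nights.
"Week" means those aligned, non-overlapping blocks — a sliding-week
reading would be stricter than the published per-length caps. Each length
then enforces its own total cap (1-night: 0; 3: 2; 7: 2; 14: 4; 21: 6; the
14-night windows also apply the per-week rule to both aligned weeks). A
valid 21-night anchor provably implies validity at L = 3, 7, 14 — each
aligned week already has at most 2 missing — so those datasets share
exactly the 21-night key set, which is the cross-length comparability the
design wants; single-night windows additionally require the anchor night
itself to be present (no cap is published for L = 1, and a window that is
entirely one missing night would be pure zero-fill), so their key set is
the subset of anchors whose first night is observed.

Within-window missing nights stay `NA` until model time: a scaler
(standardization; only sensible zero-fill target, since 0 is then the
train mean) is fit per column on observed training cells, after which
missing cells are zero-filled. Features are flattened night-major (night
1's 36 features, then night 2's, ...), recorded in the column names so
importance aggregation can invert the layout.

Splits are by subject, stratified by (label, age bin), 80/20 by default,
deterministic given the seed; singleton strata go to train with a warning.
Balanced cohorts are drawn by equalizing classes within each (age bin,
sex) cell, allocating the per-class target across cells by largest
remainder. Every evaluation path asserts train/test subject disjointness —
with overlapping windows, subject leakage would be catastrophic and
invisible.

## 5. Models

Two families with fixed, previously tuned hyperparameters: gradient-boosted
trees (200 estimators, learning rate 0.01, max depth 3; single-threaded
and seeded, so fits are reproducible) and L2-regularized logistic
regression with inverse regularization C = 0.01. The latter is fit with
`glmnet`: minimizing sum(loss) + ||w||²/(2C) is equivalent to glmnet's
mean(loss) + lambda ||w||²/2 at lambda = 1/(nC), with `standardize =
FALSE` because scaling already happened upstream. Optional 3-fold
cross-validated tuning uses folds grouped by subject — not a published
detail, but with windows overlapping across nights, ungrouped folds would
leak — selecting by mean validation AUROC with ties broken toward the
smaller-capacity specification.

## 6. Evaluation

ROC/PRC points are computed at every unique score, predictions by
score >= threshold, ties grouped; AUROC by trapezoid, AUPRC by the
step-wise rule (precision times recall increment), so a constant scorer's
AUPRC equals the prevalence exactly. The operating threshold maximizes
Youden's J = sensitivity + specificity − 1. AUROC is additionally checked
in tests against the scaled Mann–Whitney U statistic and an independent
ROC implementation.

The imbalanced protocol re-evaluates a trained model at a
general-population prevalence (default 17.9%): per repetition it samples
the control subjects needed for that prevalence — allocated to the
positive pool's age/sex strata proportionally with largest-remainder
rounding, spilling to the remaining pool when a stratum is short — then a
fixed number of windows per subject (with replacement when a subject has
fewer), and computes the curves. Across repetitions, curves are summarized
pointwise (median, 25–75%) on fixed 101-point FPR and recall grids — an
interpolation rule had to be chosen, since only shaded bands are
published. The protocol warns when the control pool cannot reach the
designed prevalence; with adequate pools its median AUROC tracks the
balanced-cohort AUROC, which is tested as a property.

## 7. Interpretation

Importance: tree gain (or mean absolute linear coefficient) per flattened
column, aggregated across the L night positions of each base feature and
normalized to sum 1 — normalization makes the sum-vs-average choice for
aggregation immaterial to the ranking. Ablation retrains on every nonempty
combination of the five feature sets (31 models — orderings of additions
collapse to combinations, since a model depends only on its feature set);
a set's contribution is its mean test-AUROC gain over the 16 subsets of
the other four sets, with the empty prefix's AUROC defined as 0.5 (a
featureless model is chance). Excluded sets' columns are removed, not
zeroed.

The chronic-condition analysis averages each test subject's predicted
probability, partitions subjects into DM / other-chronic-condition /
no-condition groups, and runs Kruskal–Wallis followed by two-sided Dunn
post-hoc tests (pairwise rank-mean z with tie correction) under
Benjamini–Hochberg adjustment; Dunn's test is implemented in-package and
verified against an independent brute-force implementation. Population-
level per-feature tests use the two-sided Mann–Whitney U and pooled-SD
Cohen's d (no small-sample correction; the published variant is not
recoverable), with the published preprocessing of the commonly used
features applied first (HR filtered to its 5–95% quantiles, RMSSD below
its 98%, TST to 1–99%; amplitude unfiltered). False-negative profiling
partitions test windows at the Youden threshold into TN/FN/TP and runs the
same omnibus + post-hoc chain per commonly used feature, skipping with a
warning when a group is empty.

## 8. Problem sizes and reproducibility

Generator defaults are the study conditions (300 subjects per class, 129
nights, 35% missingness). The test suite and the acceptance script run
scaled-down versions chosen for Monte-Carlo stability at reasonable cost:
distribution-recovery checks use 2,500 subjects per class with 4 nights
each (≥ 10⁴ nights whose effective sample size is the subject count); the
window-length performance comparison uses 50 subjects per class over the
full 129 nights, five fixed seeds, and the median across seeds (at 30 per
class the cohort-draw spread still dominates the small expected 7-to-14-
night gain); pipeline round-trip tests use cohorts of 10–30 subjects per
class. All randomness flows from explicit seeds; rerunning any
configuration reproduces cohorts, splits, fits and artifacts byte for
byte, and each written artifact carries the configuration hash.

## 9. Known limitations

Self-reported, type-agnostic labels; surrogate definitions for the
proprietary primary features; a generator that encodes the assumed class
structure rather than measured raw-signal physics (so absolute synthetic
performance should not be read as expected real-world performance); no
geography/climate adjustment; no deep-learning models; no probability
calibration beyond raw scores and no cost-sensitive thresholds beyond
Youden's J.
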