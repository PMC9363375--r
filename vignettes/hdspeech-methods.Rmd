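---
title: "Quantifying Huntington's disease severity from counting speech: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Huntington's disease severity from counting speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

Huntington's disease (HD) progressively impairs motor control, cognition and
daily function. Speech production sits at the intersection of all three:
articulation is a fine motor skill, reciting a memorised sequence backwards
loads working memory and inhibition, and pausing behaviour reflects both.
`hdspeech` quantifies these signals from a deliberately minimal speech test —
counting aloud from 1 to 20 (forward task) and from 20 to 1 with eyes closed
and hands raised (backward task, higher cognitive load) — and relates them
to the standard clinical metrics of the UHDRS battery.

The pipeline has four stages, each usable on its own:

1. **Annotation ingestion** (`readTextGrid`, `deriveSilences`): expert
   word/phone-level annotations with event categories.
2. **Feature extraction** (`extractFeatures`): 30 features per task, 60 in
   total.
3. **Prediction and validation** (`fitPredictor`, `evaluateModels`): one
   model per clinical score, evaluated over repeated grouped splits.
4. **Striatal association screening** (`striatalScreen`): information-
   theoretic dependence between each variable and striatal atrophy.

A synthetic-cohort generator (`generateCohort`, `buildCohort`) reproduces
the statistical shape of a multi-centre HD cohort so that every stage can be
exercised, and every end-to-end claim tested, without access to recordings.

# Annotations and features

Events on the word tier carry one of eight categories: `number`, four
pronunciation-error categories (paraphasia, phone perseveration, block,
prolongation — pooled as "pronunciation errors" wherever errors are
counted), `filled_pause`, `abnormal_breathing` and `vocal_noise` (the last
two pooled as "abnormal vocalizations"; together with filled pauses these
are the *collateral track*). Intervals are half-open `[start, end)` seconds.

Design choices a user should know:

- **Task duration** is last word-event offset minus first onset, not the
  file span — robust to uncontrolled recording lead-in/lead-out.
- **Silences** are gaps between consecutive word-tier events of at least
  `min_silence` seconds (default 0.1 s, the conventional pause-detection
  threshold; the threshold is a config entry because reasonable analyses
  may want 50–250 ms). Regions before the first and after the last event
  are never silences. Temporal rate (TR) of a class = summed class duration
  / task duration.
- **A mispronounced number is both things at once**: it counts as a
  pronunciation error *and* its intended label enters the pronounced number
  sequence. Sequence metrics measure ordering; error features measure
  articulation. The error ratio divides by the number of pronounced numbers.
- **Sequence targets**: forward `1..20`, backward `20..1`; the phone-level
  target concatenates the lexicon phones of the target numbers in task
  order. A French SAMPA lexicon ships for real recordings; synthesis uses an
  abstract two-phone-per-number lexicon (`P01..P40`).
- **Phonatory features consume contours, not audio**: F0 statistics are
  taken over voiced frames inside word events; intensity frames inside word
  events are normalised by subtracting their mean dB (removing
  recording-gain differences between centres) before SD and range; the F0
  range is a plain max − min over voiced frames. Pipelines without audio
  (including the synthetic generator) supply contours directly.
- **Intelligibility** is a simplified modulation-energy ratio: band-limited
  envelope energy at syllabic rates (3–20 Hz) over fast-modulation energy
  (20–80 Hz), averaged over four acoustic bands. It is a fully specified,
  deterministic index of the same family as speech-to-reverberation
  modulation-energy metrics, not a reimplementation of any published one,
  and is documented as such.

F0 tracking uses normalised autocorrelation with parabolic peak
interpolation (defaults: 60–400 Hz search range, 10 ms frames, voicing
confidence threshold 0.45); the estimator recovers clean periodic signals
within 2 Hz across 80–400 Hz.

# Clinical scores

The composite endpoint is
`cUHDRS = (TFC-10.4)/1.9 - (TMS-29.7)/14.9 + (SDMT-28.4)/11.3 + (SW-66.1)/20.1 + 10`,
the disease burden score is `age x (CAG - 35.5)`, and premanifest status is
`TFC = 13 & TMS <= 5`. Score ranges are validated on ingestion with a
choice between rejecting and clamping out-of-range values (multi-centre
tables contain typos; the default is strict rejection).

# Prediction: bounded portfolio search

Automated model search is useful here because no single model family is
uniformly best across nine heterogeneous clinical targets. The package
replaces opaque Bayesian-optimisation auto-ML with a *declared* random
portfolio over elastic-net, RBF-SVR, k-nearest-neighbour, random-forest and
CART regressors with sampled hyperparameters. The budget keeps the original
semantics — `workers x floor(totalBudget / perFitLimit)` candidates, 96
under the defaults of 24 workers, 120 s per score and 30 s per fit — but is
count-based, which makes runs bit-reproducible for a seed regardless of
hardware.

Candidates are ranked by grouped 5-fold cross-validated MAE (participants
never straddle folds; the CV scheme is a package choice, as is MAE as the
selection metric, matching the reporting metric). The top `ensembleSize`
candidates are combined by greedy forward selection with replacement on
their out-of-fold predictions; the selection is kept only while it improves,
so the ensemble's CV error never exceeds the best single candidate's.
Predictions are clipped to each score's valid range. Missing feature values
are imputed with training-set medians (robust for skewed duration
features); features are z-standardised with training-set statistics.

Three input sets mirror the study design: speech features + demographics
(sex, age, CAG repeats, DBS), demographics alone (the genetic/demographic
baseline), and the training-set mean of the target ("cohort mean", the
classical replication baseline). Ablation kinds `forward_only` /
`backward_only` use the 30 per-task features without the demographics
block, so the comparison isolates the feature subsets themselves.

Elastic-net importance fits a linear model with mixing parameter 0.5 at the
1-SE cross-validated regularisation strength, flips coefficient signs so a
larger weight always reads as more impairment, and z-scores weights across
features within each score.

# Validation

Splits are at the participant level: every exploration-cohort participant
always trains; per repeat, `floor(0.8 n)` of the validation-cohort
participants train and the remainder test (67 validation participants give
53/14; with 36 exploration participants the train set has 89). All visits
of a participant land on one side. Errors are summarised per repeat by MAE
and by ICC(2,1) — two-way random effects, absolute agreement, single
measurement:

`ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, `k = 2`.

The ICC of a constant predictor is undefined (zero rater variance) and is
reported as `NA`. Models are compared by two-sided Wilcoxon signed-rank
tests on paired per-repeat MAEs (the per-repeat pairing is a package
choice; pooling per-visit errors would mix split variability into the
test), Bonferroni-corrected over all score x pair tests in a report.

# Striatal association screening

Dependence between each variable and the striatal volume percentage is
measured with the equicharacteristic-matrix information coefficients: over
grid shapes `(k, l)` with `k·l <= B(n) = n^0.6`, one axis is
mass-equipartitioned and the other optimised by dynamic programming over
clump boundaries (candidate boundaries capped at 5k); each entry is the
maximal mutual information normalised by `log2 min(k, l)`. **TICe** (the
entry sum) screens for significance — it has high power; **MICe** (the
entry max) measures strength — it is highly equitable across relationship
shapes. Both orientations are computed and combined, making the statistics
symmetric; estimator parameters follow the published defaults (exponent
0.6, clump factor 5). The core is implemented in C++ and validated against
exhaustive partition enumeration at small sample sizes.

Significance uses permutation p-values with +1 smoothing, and family-wise
error is controlled by the maximum statistic: the same volume permutation
is applied to every variable in a round, and the adjusted p of a variable
counts rounds whose *family maximum* reaches its observed statistic. This
respects the strong correlation among speech features. Speech features and
clinical variables are corrected as separate families (correcting jointly
would let the typically stronger clinical signals mask speech effects; both
families are reported). The default of 2000 permutation rounds keeps the
adjusted-p resolution at 5e-4; any count of at least 100 is accepted.

# The synthetic cohort

A single latent severity scalar drives everything; HD clinical scores are
mutually correlated facets of one process, and a shared latent makes
cross-stage ordering claims well-posed. Severity is the standardised
disease burden score plus Gaussian noise (SD 0.8), restandardised, so
demographics predict severity imperfectly while speech features — which see
severity itself — can beat them.

Calibration constants are fixed to the cohort they emulate: 103
participants (36 exploration, 67 validation), age 50.7 (11.2) years in
[27, 88], CAG 44.0 (3.6) with floor 36, 63/103 female, about one
participant in five with a second visit, and the nine score links set to
the cohort means/SDs with severity loadings of magnitude 0.6–0.75 (typical
cross-domain disease correlations; chosen once, not tuned).

Timelines emit the 20 target numbers with log-normal inter-number gaps
whose location rises with severity; the gap location solves
`20 mu_number + 19 E[gap] = 10.7 s` (forward) and `15.6 s` (backward)
analytically, including the variance corrections for the log-noise and the
severity slope, so cohort-level mean durations match the calibration
targets by construction. Omission and perseveration probabilities are equal
(logistic in severity), so their expected duration effects cancel.
Backward slopes exceed forward ones (gap slope 0.65 vs 0.55; logistic
slopes x1.25) — the generator *encodes as an assumption* that backward
counting is the more sensitive task, which the ablation tests then verify
end to end. Collateral events are placed inside sufficiently long gaps and
never alter total task time. Striatal volume percentage falls linearly in
severity (slope 0.12 %/SD, noise 0.12) around a 1.3% baseline.

What the generator does **not** emulate: multi-speaker acoustic
variability, annotation disagreement, heavy-tailed real-world pause
distributions (between-subject duration SDs land near 2.5/4.5 s versus the
6 s scale of real cohorts: a single latent factor cannot reproduce full
clinical heterogeneity), language-specific phonology, or missing data.
Passing tests therefore demonstrate the *correctness and sensitivity* of
the pipeline under a plausible disease model, not clinical performance on
real recordings.

# Numerical choices and degenerate inputs

- Sequence metrics: empty vs empty is similarity 1 / distance 0; ties in
  the longest-common-block search resolve to the first leftmost block.
- `ICC` requires n >= 3 and errors on zero-variance raters rather than
  returning a sentinel.
- MICe/TICe return 0 (with a warning) for constant inputs; equipartition
  keeps tied values in one row; points with equal x can never be split
  across bins.
- The greedy ensemble is evaluated on out-of-fold predictions only;
  selection stops improving rather than growing unboundedly (25 rounds).
- Predictions are clipped to the score's valid range; scores with no
  defined ceiling clip at 0 only.
- All randomness flows from a single integer seed per entry point; repeated
  splits derive one sub-seed per repeat.

# Problem sizes used by the test suite

The suite exercises the protocol at sizes chosen to keep the full run on a
laptop-class single core comfortable while leaving every statistical claim
testable: sequence-metric oracles are exhaustive over the binary alphabet to
length 6; ICC and MICe/TICe oracle comparisons use 100 random instances
each (n <= 15, grid bound 6 for the exhaustive enumeration); family-wise
error control is measured over 500 global-null datasets (n = 20, 60
features, 199 permutation rounds — the round count is a config with floor
100); ordering claims use the default 103-participant cohort with the full
50 repeated splits and a 12-candidate search budget per fit. The
96-candidate default budget semantics are asserted separately through
`minCandidateCount`.

# Known limitations

- The intelligibility index is a simplified modulation-energy ratio, suited
  to relative comparisons within a cohort, not an absolute intelligibility
  score.
- The portfolio search is count-based; wall-clock budgets would make runs
  hardware-dependent and are deliberately not the default.
- ICC confidence intervals are not reported (point estimates only).
- Cross-cohort transfer and longitudinal change modelling are out of scope;
  visits are analysed cross-sectionally.
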