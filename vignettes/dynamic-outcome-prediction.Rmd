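---
title: "Dynamic prediction of reliable improvement in iCBT: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic prediction of reliable improvement in iCBT: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbtri)
```

This vignette is the package's account of its own methods: the outcome and
models it implements, what the synthetic cohorts do and do not emulate, the
numerical conventions, and the places where the design was genuinely open
and a choice had to be made.

## The outcome: reliable improvement under censoring

Both instruments are sums of 0–3 ordinal items (PHQ-9: nine items, total
0–27; GAD-7: seven items, total 0–21), completed once per *review period* —
the unit of prediction time, roughly 1.8 weeks of calendar time. Treatment
is evaluated over at most eight review periods.

Reliable improvement (RI) is the Jacobson–Truax reliable-change criterion
used in routine outcome monitoring: a decrease of at least 6 PHQ-9 points
(respectively 4 GAD-7 points) between the first completed measure and the
last available one, with no disqualifying deterioration of 4+ GAD-7
(respectively 6+ PHQ-9) points on the companion measure. Three reading
conventions are worth making explicit, because the verbal definition leaves
them open:

* **Disqualification is inclusive**: a companion increase of *exactly* the
  disqualifying threshold (e.g. +4 GAD-7) already vetoes the label. We read
  "no increase ≥ k" literally. `label_reliable_improvement()` implements
  this and the test suite pins it against a brute-force oracle on the full
  integer grid of score pairs.
* **Baseline is the first completed measure** (review 1), not an intake
  assessment.
* **LOCF**: for clients who stop early, the last observed measure at or
  before review 8 defines the outcome (`locf_final_scores()`); observations
  past review 8 never influence the label.

Severity bands: only the mild band is externally fixed (PHQ-9 0–8, GAD-7
0–6). The moderate/severe boundary defaults to conventional instrument
banding (PHQ-9 moderate 9–16 / severe 17–27; GAD-7 moderate 7–14 / severe
15–21) and is overridable in `assign_severity_band()`, since subgroup
definitions vary across services.

## The synthetic cohort generator

The generator (`sample_cohort()`) is first-class, tested code: it defines
the study conditions under which every downstream claim is verified.
Per client it draws:

1. a baseline severity band (default mixture 15 % mild / 50 % moderate /
   35 % severe, shared by both instruments — referral populations skew
   moderate-to-severe) and integer baselines uniform within band;
2. a latent **trajectory archetype** shared by the two instruments:
   steady improver, sudden-gain improver, late improver, non-responder, or
   deteriorator. Curves are cumulative expected changes in the total score
   (PHQ-9 points); GAD-7 reuses the latent curve scaled by
   `gad_change_scale`. The sudden-gain curve crosses the reliable-change
   threshold by the second review, the steady curve around the fourth, the
   late curve near the end; these shapes mirror the trajectory modes that
   error analyses of outcome predictors typically surface (early sudden
   gains, late gains, regression to baseline);
3. total-score trajectories with two noise layers: per-archetype curve
   noise (`curve_sd`, default 1.5 points) plus observation noise
   (`noise_sd`, default 1.0), sharing one latent stream across instruments
   with correlation `score_correlation` (default 0.6). Neither the
   dropout–outcome dependence nor the cross-instrument correlation of real
   cohorts is published; both are configurable statements about the
   simulation, not claims about any platform;
4. item allocations: totals are partitioned into 0–3 item scores by
   sampling unit "slots" without replacement (`allocate_items()`), which is
   exact (sums match totals by construction) and uniform over feasible
   allocations. Trajectories are generated on totals and items are
   allocated downward because the outcome operates on totals; item-level
   structure only matters for the `Qc` feature set;
5. interaction counts: a negative-binomial total per review (mean
   `engagement_rate` x a lognormal client engagement level, dispersion
   1.5) thinned multinomially across a ~30-type active subset of the
   1133-type taxonomy with 1/rank weights — overdispersed and sparse, like
   platform event logs;
6. review intervals: Gaussian with mean 1.8 / SD 0.24 weeks, truncated at
   0.5. Intervals are metadata only; prediction points are review indices;
7. dropout: a geometric per-review hazard from the second review onwards
   (default 0.6, so ~60 % of clients have fewer than three reviews — the
   censoring regime that makes dynamic prediction hard), optionally tilted
   by improvement-so-far through a logistic link
   (`dropout_improvement_beta`, default 0 = independent).

**Prevalence calibration.** `calibrate_prevalence()` matches the labeled RI
prevalences to targets (defaults 26 % PHQ-9, 38 % GAD-7) with two monotone
bisections — total improver mass against the PHQ-9 target, then the GAD-7
change scale against the GAD-7 target — on seeded pilot cohorts. The
shipped defaults are one frozen output of this procedure; the test suite
re-checks them on an independent 5000-client cohort at ±0.03.

What the generator does **not** emulate: free-text or supporter behaviour,
demographic covariates, real content taxonomies, item-level response
styles, calendar-time effects, or measurement reactivity. Passing tests
therefore demonstrate that the pipeline is correct and that the models can
recover signal under realistic censoring and class imbalance — not that
any accuracy level transfers to platform data.

## Featurization

Four per-review sequence encodings (`build_sequence_features()`): `Q` the
target instrument's total (dimension 1; optionally 2 with the companion
total), `Qc` the item scores (9/7), `I` the per-review (not cumulative)
interaction counts (1133), `I+Q` their concatenation (1134). Static
benchmarks instead use a length-16 vector (`build_benchmark_vector()`):
totals at reviews 1–8, zero where unobserved (avoiding imputation bias),
plus eight availability indicators. Missing intermediate reviews keep value
0 / indicator 0, treated as missing-at-random. For single-target models the
companion total is excluded by default (input dimension 1), configurable —
the alternative reading (both totals) is available via
`include_companion = TRUE`.

## Models

**Recurrent classifier** (`train_rnn()`): a three-layer many-to-one
network — linear input map, one LSTM layer with a 50-dimensional hidden
state and dropout 0.4 on the final hidden state during training, and a
linear softmax over the two outcome classes — trained with Adam on
cross-entropy. "Three layers" admits several readings (stacked recurrent
layers, dropout between them); we use the parsimonious input-map → LSTM →
softmax reading and note the ambiguity here. The implementation is
batched pure-R matrix code with hand-derived backpropagation through time,
verified against numerical gradients to ~1e-10 in the test suite.

*Prefix augmentation*: each client observed at reviews 1..n contributes n
training sequences (lengths 1..n) sharing the end-of-treatment label. This
is what makes a single model answer at every review period; how the
original training examples were constructed is not published, and this
choice is also applied to the static benchmarks for comparability.

Numerical conventions: features are standardized on the training set
(interaction counts log1p-transformed first); the forget-gate bias starts
at +1; padded time steps are masked in both passes so the final state is
each sequence's state at its own last valid step; model selection is by
validation accuracy with early stopping (patience 10, not externally
specified); a non-finite loss aborts with the training history attached.
Training is deterministic given the configuration seed.

**Static benchmarks** (`train_static_classifier()`): logistic regression
(`stats::glm`), random forest (`ranger`, 300 trees), gradient boosting
(`xgboost`, 150 rounds, depth 3, learning rate 0.1), all on the length-16
encoding, one row per (client, observed review), single-threaded and
seeded.

**EMA baseline** (`ema_model()`): exponential smoothing
`s_k = alpha x_k + (1 - alpha) s_{k-1}` of each instrument's totals up to
the prediction time; the one-step forecast stands in for the final score,
is rounded half-up to an integer, clipped to the instrument range, and
pushed through the RI criterion. The smoothing weight is not published;
the default is `alpha = 0.6` (trend-following but noise-damping) and is
reported in all outputs. The one-step forecast is used rather than an
extrapolation to review 8; a linear-trend variant was considered and
rejected as a default because it is badly behaved on two-point prefixes.

**No leakage** is a contract, not an aspiration: `predict_at_time()`
consumes only observations at or before the prediction review, and the
acceptance suite asserts bit-identical predictions under arbitrary
modification of later reviews for every model kind.

## Evaluation

`stratified_evaluation()` computes accuracy, sensitivity, specificity,
AUROC (rank statistic, ties counted half) and sensitivity at fixed 90/95/97
% specificity, per review period, per baseline-severity band, and pooled.
"All t" rows pool prediction-time points (each client contributes one
evaluated prediction per observed review); a per-client-averaged variant
sits behind `per_client = TRUE`. Conventions:

* **Operating points**: for each specificity floor we take the threshold
  attaining the *smallest* specificity still at or above the floor (the
  most sensitive admissible point). When only the degenerate all-negative
  threshold qualifies (e.g. all scores tied), the point is flagged
  unattainable rather than silently reported. Whether published operating
  points of this kind are chosen on validation or test scores is generally
  unstated; thresholds here are explicit outputs, so either protocol can
  be reproduced — freeze a validation threshold and apply it to test
  scores, or sweep in-sample.
* **Uncertainty**: percentile intervals from a cluster bootstrap that
  resamples whole clients, because repeated predictions for one client are
  strongly correlated; resampling prediction points would understate
  uncertainty. Degenerate resamples (a single class) are skipped and
  counted.
* **Empty denominators** (no positives in a stratum) yield `NA`, never 0.

`km_time_to_improvement()` estimates time to *sustained* reliable
improvement — the first review from which the RI criterion (versus
baseline) holds at every subsequently observed review — with the
product-limit estimator (`survival::survfit`), censoring at the last
observed review, stratified by baseline severity band. A worked six-client
censored fixture in the tests pins the estimator to a hand-computed table.

## Error analysis

`classify_errors()` partitions hard predictions at a fixed review period
(default t = 3, the earliest time at which predictions are typically
surfaced to supporters) into the 2x2 cells, carrying full trajectories.
`trajectory_summary()` averages trajectories pointwise over the clients
observed at each review index — ragged alignment, since dropout makes
lengths unequal and the alternative (complete-case alignment) would bias
the mean toward completers. `threshold_proximity()` quantifies the
clustering of true final changes around the RI threshold change (−6 PHQ-9,
−4 GAD-7): prediction errors concentrate near the threshold, where the
true change is within measurement error of the criterion.

## Orchestration and reproducibility

`run_experiment()` runs simulate → label → split (70:20:10, stratified
jointly on both outcome labels) → train → evaluate → error analysis from
one configuration. Stage seeds are derived by hashing (global seed, stage
name), so adding a stage never perturbs the random streams of the others;
the manifest records content hashes of every deterministic artifact.

## Problem sizes

The shipped verification runs use cohorts of 5000 clients for generator
calibration checks, 2000–2500 for model-level checks (signal recovery on a
noiseless separable cohort; the rising accuracy-over-time profile on the
default noisy cohort), and 20–300 for unit-level checks. These sizes were
chosen as the smallest at which the binomial/bootstrap tolerances used in
the assertions are comfortably informative.

One design note on the separable benchmark (`separable_cohort_config()`):
it pairs *sudden-gain* improvers with non-responders. With gradual
improvers the first two reviews of the two classes overlap, and a single
prefix-pooled linear model provably cannot separate later prefixes while
also fitting the uninformative early ones (the class signal lives in score
differences; with varying baselines no shared linear boundary exists). The
sudden-gain archetype makes the constructed cohort separable at every
prediction time from which change is observable — which is the premise of
a separability check.

## Known limitations

* Review indices are assumed contiguous within a record for sequence
  models (the generator guarantees this); externally supplied cohorts with
  internal gaps are supported by the benchmark encoding but the sequence
  position then differs from the review index.
* The LSTM is CPU-bound pure R; it is comfortable at the cohort sizes
  above (minutes), not at platform scale (tens of thousands of clients
  with 1134-dimensional inputs).
* Calibration matches marginal prevalences, not the joint distribution of
  (PHQ-9, GAD-7) outcomes, and the generator's archetype mixture is a
  modeling convenience, not an estimate of real trajectory-class
  frequencies.
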