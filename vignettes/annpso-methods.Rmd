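---
title: "Training a neural obesity-risk classifier by particle swarm optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training a neural obesity-risk classifier by particle swarm optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(annpso)
```

## The model

The package classifies survey participants into seven obesity-risk
levels. The label is defined by body mass index, `BMI = weight /
height^2` (kg/m^2), partitioned into half-open intervals: insufficient
weight below 18.5, normal weight [18.5, 25), overweight level I
[25, 27.5), level II [27.5, 30), obesity type I [30, 35), type II
[35, 40), type III from 40 upward. The WHO tables print closed-looking
ranges ("18.5–24.9"); we use half-open intervals so that every positive
BMI (24.95, say) belongs to exactly one class. The WHO's single
overweight band is split at 27.5 kg/m^2, the convention of the survey
data this schema mirrors; a strict six-class WHO table is available via
`bmi_class_table("who")`.

The classifier itself is a fully connected network — by default
16 engineered inputs → 128 → 64 → 32 → 7, ReLU hidden activations,
softmax output — whose entire parameter vector (weights and biases,
layer by layer, row-major weights then biases) is treated as a single
point in R^d and optimized by a particle swarm. Each particle `i`
carries a position `x_i` (a candidate weight vector) and velocity
`v_i`, updated per iteration `k` as

```
v_i <- w(k) v_i + c1 r1 (P_i - x_i) + c2 r2 (G - x_i)
x_i <- x_i + v_i
```

where `P_i` is the particle's best visited position, `G` the swarm's,
`r1, r2` are Uniform(0,1) draws, and the inertia weight decays linearly
from `w_max` to `w_min` over the iteration budget:
`w(k) = w_max - ((w_max - w_min)/k_max) k`. The fitness minimized is
the mean squared error between the network's softmax outputs and
one-hot encoded labels on the (SMOTE-balanced) training split. MSE on
probabilities is bounded in [0, 1] and is zero exactly at a perfect
one-hot fit; cross-entropy is available as an alternative
(`loss = "cross_entropy"`).

### Why a swarm instead of backpropagation

Gradient training of small tabular networks can stall in poor basins
and is sensitive to initialization. A swarm explores many weight
configurations in parallel and needs only fitness evaluations, not
gradients. The cost is scale: progress per evaluation degrades in high
dimension, which drives several of the design choices below.
Backpropagation is deliberately not part of the training path.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `c1`, `c2` | 2, 2 | cognitive / social acceleration (dimensionless) |
| `w_max`, `w_min` | 0.9, 0.2 | inertia-weight range, linear decay |
| `n_particles` | 40 | swarm size |
| `k_max` | 100 (`pso_config`); 150 in the pipeline benchmark | iterations |
| `bounds` | [−1, 1] (`pso_config`); [−0.25, 0.25] in `train_ann_pso` | per-dimension position box |
| `v_max` | half the bound width | componentwise velocity clamp |
| `r_mode` | `"particle"` (`pso_config`); `"dimension"` in `train_ann_pso` | granularity of the r draws |
| `restarts` | 2 (`train_ann_pso`) | independent swarm runs, best kept |
| hidden stack | 128-64-32, ReLU | network architecture |
| SMOTE `k` | 5 | nearest neighbors for interpolation |
| split | 0.70 / 0.15 / 0.15, stratified | train / validation / test |

The swarm coefficients, inertia range, particle count and hidden stack
are the tuned values of the study this pipeline operationalizes and are
kept as package defaults. The remaining choices were open, and the
trainer resolves them as follows.

**Iteration index.** The schedule's `k` is 0-based: the first update
uses exactly `w_max` and `inertia_weight(k_max)` equals `w_min`
exactly. The implementation uses the convex-combination form
`w_max (1 − k/k_max) + w_min (k/k_max)`, algebraically identical to the
formula above but floating-point-exact at both endpoints.

**Per-dimension stochasticity.** With scalar `r1, r2` a particle moves
inside the 3-dimensional span of its velocity and two attraction
vectors — a severe restriction when the position is a 13,000-dimensional
weight vector. `train_ann_pso` therefore draws `r1, r2` per dimension
(the common formulation in high-dimensional applications); the scalar
mode remains the low-level default and is selectable.

**Weight-scale bounds.** Inputs are standardized (see below), so useful
network weights are small; a [−0.25, 0.25] box keeps initial logits
moderate. With wide bounds the softmax saturates, the MSE surface
becomes nearly flat in most directions, and the swarm stalls — we
measured roughly 0.19 training MSE (barely better than the 6/49 of a
uniform predictor) with [−1, 1] boxes versus ~0.03 with the narrow box
at identical budgets.

**Velocity clamp and position clip.** `c1 = c2 = 2` sits at the edge of
the divergence region of the standard PSO stability analysis; the
componentwise clamp at `v_max` and clipping to the box prevent
blow-ups. Both are configurable off.

**Restarts.** Swarm quality varies run to run. The trainer runs two
independent swarms (seeds derived deterministically from the main seed)
and keeps the one with the better final training fitness — plain
multi-start model selection that never sees validation or test data.

**Scaling.** Model inputs are z-scored by default
(`feature_config(scaling = "zscore")`), with statistics fitted on the
training split only. Zero-mean inputs noticeably improve swarm
convergence over min-max [0, 1] inputs (all-positive inputs force
first-layer activations into correlated regimes). Min-max scaling
remains available. The engineered scores keep their own internal
min-max conventions: Activity Balance rescales technology time onto the
physical-activity range [0, 3] so the two terms are commensurable, and
Tech Usage Score rescales it to [0, 1] before dividing by age.

**Iteration budget.** `k_max` is not fixed by the study; 100 is the
generic default, and the shipped benchmark uses 150, where the
convergence trace has flattened at problem sizes of a few thousand
records (40 particles × 150 iterations ≈ 6,000 fitness evaluations,
each a full forward pass over the training split).

## The data pipeline

`train_ann_pso()` runs: cleaning (drop records with missing fields,
exact duplicates, and 1.5×IQR outliers on age, height, weight) →
stratified 70/15/15 split → feature engineering fitted on the training
split (Meal Habits = FCVC × NCP; Activity Balance = FAF − scale(TUE);
Tech Usage Score = scale01(TUE)/age; transport mode recoded to an
activity ordinal automobile/motorbike 0, public transport 1, walking 2)
→ height removal → scaling (train-fitted) → SMOTE balancing of the
training split only → swarm optimization → evaluation on validation and
test. The survey codebook does not say whether engineered scores
replace their ingredients; we keep the originals alongside by default
(`keep_original`). SMOTE interpolates uniformly on segments between
same-class nearest neighbors (k = 5, the original formulation) and is
never applied to validation or test data; whether the original study
balanced before or after splitting is unstated, and balancing only the
training folds is the leakage-safe reading. Ten-fold stratified CV
utilities are provided; per-fold swarm refits are optional
(`cv = TRUE`) because each fold repeats the full optimization — the CV
report is metric variance, not model selection.

The inverted published coding of FAVC (**0 = Yes, 1 = No**) is kept
exactly as printed so that files round-trip unchanged; the schema table
(`obesity_schema()`) flags it.

## The synthetic cohort generator

The survey datasets themselves (2,111 and 20,758 records, merged) are
not shipped; `generate_obesity_data()` emulates their schema and the
study conditions. Its construction:

* class sampled from mildly imbalanced weights (defaults ~0.13–0.17,
  obesity type I largest; the published distribution figure prints no
  counts, so the weights are a documented default);
* height gender-conditional Normal (male 1.75 m, female 1.62 m);
* BMI uniform inside the class's interval (floored at 14, capped at 50
  kg/m^2), with a small interior margin so that rounding weight to
  0.01 kg can never move a record across a class boundary;
* weight set to `BMI × height^2` — so with zero label noise the label
  is *exactly* recoverable from weight and height (the ceiling check:
  any sane classifier trained with height approaches 100%);
* every habit feature drawn from an adiposity-conditional
  ordered-threshold (cumulative-logit) model: the probability of being
  at or beyond each level is a steep logistic step in the record's
  continuous adiposity score, with stages staggered across the range
  (vegetables drop early; family history and calorie monitoring flip
  around overweight; activity collapses around obesity I; alcohol and
  transport change last);
* age increases with adiposity (18→36 years across the range, sd 2.5);
* an optional `label_noise_rate` reassigns that fraction of labels
  uniformly at random.

The staggered thresholds are what keeps the seven classes learnable
*after* height removal: jointly, the habit features act as a thermometer
code for adiposity. This is a deliberate idealization — real survey
responses are far noisier, correlations with adiposity are weaker and
partly non-monotone, and real features carry redundancy and reporting
artifacts that this generator does not model. Passing the packaged
benchmark therefore demonstrates that the optimizer and pipeline work
end-to-end on a recoverable signal; it does not certify any accuracy
level on real survey data. The generator's parameters were fixed by
calibrating against reference classifiers (a random forest and a
multinomial logit, neither part of the shipped model) until the task
was demanding but solvable without height, and are not tuned further.

Ceiling measurements under the frozen defaults: reference classifiers
without height reach ~0.92–0.93 test accuracy; the swarm-trained
network reaches ~0.90 on the packaged benchmark (3,000 records), with
chance at ~1/7 under fully randomized labels.

## Numerical choices and degenerate inputs

* Softmax is computed with row-max subtraction; rows sum to 1 within
  1e-12.
* Argmax ties break toward the lowest class index (deterministic
  predictions).
* Zero-denominator metrics (a class never predicted and never true)
  report 0 with an `undefined` flag rather than NaN.
* ROC curves take one point per distinct threshold plus (0,0) and (1,1)
  anchors; AUC is trapezoidal; PR curves anchor recall 0 at the first
  observed precision. A class absent from the truth vector is skipped
  with a warning and excluded from macro averages.
* A degenerate scaler (constant feature) maps to 0 instead of dividing
  by zero; a single-member minority class falls back to
  duplicate-with-jitter in SMOTE, with a warning.
* Non-finite fitness values are treated as +Inf (the particle simply
  never becomes a best) with a warning.
* Model JSON stores weights at 17 significant digits, making
  save → load bit-exact; artifact writes go through a temp-file +
  rename so failed runs leave no partial outputs.
* All stochastic steps (generation, splitting, SMOTE, swarm) run under
  scoped seeds (`withr`), so equal seeds reproduce byte-identical
  artifacts without disturbing the caller's RNG state.

## Problem sizes

The packaged benchmark trains on 3,000 synthetic records (≈2,100
training rows before SMOTE, ≈3,500 after) with the full 128-64-32
architecture (12,999 parameters at 18 inputs) for 2 × 150 iterations of
40 particles. The test suite uses smaller cohorts (a few hundred
records) and narrow hidden layers for structural checks, reserving the
full benchmark for the end-to-end accuracy test.

## Known limitations

* PSO scales poorly with parameter count; the default architecture is
  near the practical limit for gradient-free training, and accuracies
  trail what backpropagation could reach on the same data.
* The generator's class-conditional structure is idealized (see above);
  no claim transfers to real cohorts without retraining and
  revalidation.
* SHAP-style attributions are not implemented; permutation importance
  is the shipped interpretability tool and measures marginal, not
  interventional, contributions.
* The 10-fold CV report is sequential and therefore expensive with
  swarm refits; it is off by default.
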