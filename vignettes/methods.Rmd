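---
title: "Methods: cascaded synthetic questionnaire generation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded synthetic questionnaire generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthq)
```

## Overview

`synthq` generates synthetic responses for a six-questionnaire ME/CFS
battery. Given real SF-36 item answers, a five-step cascade of per-question
class-weighted classifiers produces synthetic HAD, SCL-90-R, FIS8, FIS40 and
PSQI answers (186 items). This vignette documents the model and its
assumptions, the knobs that matter, the synthetic-cohort generator used in
place of the (non-public) hospital registers, the numerical choices, and the
limitations.

## The battery schema

The bundled schema encodes six instruments: SF-36 (36 items, answers 1–6),
HAD (14 items, 0–3), SCL-90-R (90 items, 0–4), FIS8 (8 items, 0–4), FIS40
(40 items, 0–4) and PSQI (34 items, 0–3) — 222 items, and 38 subscales
tagged with a thematic *subject* (Physic, Pain, Emotional, Mental, Anxiety,
Depression, Cognitive, Sleep quality, ...).

Two caveats are deliberate:

* **Item membership is a stand-in.** The licensed instruments do not ship a
  machine-readable item-to-subscale key, so the default schema assigns
  contiguous item blocks whose sizes are consistent with each instrument's
  published structure (e.g. HAD anxiety = items 1–7, depression = 8–14;
  SCL-90-R nine 10-item dimensions plus three global indices over all 90
  items). Every subscale is scored as the **sum of member items**: the
  analyses downstream (correlation thresholding, ordering) depend only on
  monotone aggregates, not on the instruments' norm-based scoring. Users
  with the licensed keys can supply the exact mapping as a JSON/YAML schema
  file (`load_schema()`).
* **Block-level missingness.** A record either has a questionnaire complete
  (a validated register) or not at all; partial blocks are rejected at load
  time (or dropped to missing under the `"drop-partial"` policy). This
  mirrors how such registries validate forms, and it is what makes the
  per-step complete-case counts shrink down the cascade.

## Subscale graph and cascade order

Subscale scores are correlated pairwise (Pearson, pairwise-complete
observations; a complete-case switch exists, `pearson_matrix(use =
"complete")`). An edge joins two subscales when `|r| >= tau`, default
`tau = 0.5` — the conventional boundary of a moderate correlation; strong
*negative* correlations also count as relationships. Pairs with fewer than
3 pairwise-complete records or a constant column get no edge.

The generation order is greedy coverage from the input questionnaire:
repeatedly append the questionnaire `j` maximizing the fraction of `j`'s
subscale nodes adjacent to at least one node of the already-selected
questionnaires. The *union* of selected questionnaires is used as the source
set because the cascade concatenates every previously generated block into
the next step's features. Ties are broken by (1) larger absolute number of
covered nodes, (2) smaller own node count, (3) name; `cascade_order()`
attaches the full candidate trail for audit. Isolated questionnaires get
coverage 0 and sort last — in register-like data that is PSQI, whose
sleep-quality subscales barely correlate with the rest of the battery.

## The cascade

Step *k* trains one classifier per item of the *k*-th target questionnaire
on the records whose real input blocks **and** real target block are all
complete. Features are the real SF-36 block concatenated with the
*synthetic* outputs of previous steps, so each step is trained under the
same distribution it will see at generation time (a `teacher_forcing`
switch substitutes the real prior blocks, for ablation). Under the default
schema the feature dimensions are 36 → 50 → 140 → 148 → 188 and the targets
14, 90, 8, 40, 34 — 186 question models in total.

Answer categories are strongly imbalanced in real registers, so every
classifier is trained with balanced class weights
`classWeight_i = n / (classes × count_i)`. At the published supports of the
first HAD question (66/886/807/562 over answers 0–3, n = 2321) this gives
weights 8.79 / 0.65 / 0.72 / 1.03; the source table prints 8.80 and 0.66
for the first two, which the formula does not reproduce at printed
precision — the formula as stated is implemented, and the two printed cells
are treated as rounding artefacts.

Prediction defaults to **argmax** (a deterministic generator); `mode =
"sample"` draws each answer from the classifier's class scores under a
seed. Argmax intentionally sharpens toward each item's conditional mode,
which is the right choice for single-record imputation but distorts
*marginal* answer distributions of weakly predictable items; sampling mode
is what preserves marginals, and it is what the distribution-fidelity test
uses.

### Backends

The backend contract is `fit(features, labels, class_weights, hyperparams,
seed)` plus per-label scores for new records. Four are shipped:

* **`multinomial`** (default): class-weighted multinomial logistic
  regression fitted by full-batch gradient descent with momentum
  (zero initialisation, standardized features, 150 iterations, learning
  rate 0.3, L2 `1e-4`). It has no random state at all, which gives the
  package its end-to-end bitwise determinism, and it is fast enough to fit
  186 models on a 2000-record cohort in about a minute on one CPU.
* **`mlp`**: a feed-forward ReLU network with softmax output, weighted
  cross-entropy, Adam, dropout on the leading hidden layers, and early
  stopping on **validation macro recall** over a 20% stratified split — the
  recall monitor is what counteracts imbalance collapsing rare answers.
  `default_step_hyperparams()` ships the five per-step configurations
  (hidden layers 400/400/200/100 …, dropout depth, epoch budgets
  3000–4000, patience 300–400). These budgets are sized for register-scale
  data; tests exercise the backend at small settings.
* **`xgboost`**: gradient-boosted trees (depth 4, eta 0.3, 50 rounds by
  default), included because boosted trees and neural networks perform
  similarly on this kind of structured data.
* **`regressor`**: class-weighted linear least squares whose continuous
  prediction is rounded *half away from zero* then clamped to the item's
  answer rank. It exists for the regression-versus-classification
  comparison — rounded regression inflates the questionnaire-total mean
  error badly relative to classification — and is not recommended for
  generation.

A target item observed with a single class yields a constant predictor (with
a warning); steps refuse to train below 30 complete records by default.

## Validation metrics

* `classification_report()`: per-label precision, recall, harmonic-mean F1
  (zero where undefined), supports, accuracy, macro and support-weighted
  averages.
* `mean_error()`: `100 × (Σ synthetic − Σ real) / Σ real`, the signed
  percentage by which the synthetic block mis-states the questionnaire's
  total answer mass; negative = under-scoring.
* `sum_ttest()`: per-item column sums form one series per block; a
  two-sided Welch t-test compares the two series (a paired variant is
  available). Identical series give p = 1 by convention; two constant but
  unequal series give p = 0 with a warning. The p-value reading of this
  statistic is a judgement call; the test statistic itself is standard.
* `evaluate_cascade()`: per step, all (record, question) decisions are
  pooled into one confusion matrix; accuracy is the pooled exact-match
  rate, while precision/recall/F1 are macro averages over the pooled
  labels. Pure micro-averaging would make precision = recall = F1 =
  accuracy in single-label multiclass classification, so macro averaging
  over the pooled label set is used for those three rows; the convention is
  noted here and in the function documentation.

## The synthetic-cohort generator

Real registers cannot be bundled, so `generate_cohort()` draws cohorts from
a latent-trait model: per record, a vector of subject traits `z` from a
zero-mean unit-variance Gaussian with a chosen subject correlation matrix;
per item, a latent `u = λ·z[subject(item)] + sqrt(1 − λ²)·ε`, discretised
onto the item's answer rank by equal-probability thresholds (so marginals
are uniform unless per-item probabilities are supplied, e.g. to emulate the
66/886/807/562 imbalance of the first HAD question). Missingness is a
seeded per-(record, questionnaire) Bernoulli. Same spec + seed means a
bitwise-identical cohort.

`default_paper_like_spec()` plants the structure observed on register data:

* a physical cluster (Physic, Pain, General health, Vitality, Social;
  r = 0.80 within), a psychopathology cluster (Mental–Anxiety–Depression,
  r = 0.80–0.85) bridged to SF-36 through the Emotional trait (r = 0.75 to
  Anxiety/Depression), Cognitive weakly coupled (0.35), Sleep quality nearly
  uncoupled (0.20);
* item loading λ = 0.8 throughout;
* per-questionnaire retention mirroring the relative register counts of the
  real battery (SF-36 0.930 … PSQI 0.777, PSQI lowest);
* SF-36's mental-health items mapped to the **Emotional** trait rather than
  the shared Mental trait. This is the one deliberate distortion: on real
  data HAD tracks the SCL-90-R dimensions far more closely than the SF-36
  mental subscales do, and a single shared Mental trait cannot express that
  asymmetry — it would force SF-36 to cover every SCL-90-R node whenever it
  covers HAD.

On cohorts of 2000 records this reproduces the qualitative graph narrative:
SF-36 covers all three HAD nodes; HAD covers all twelve SCL-90-R nodes;
SF-36 reaches only a minority of SCL-90-R (its anxiety/depression
dimensions and, because they sum all 90 items, the three global indices —
so 7 of 12 here, where the real-data account reports the four
anxiety/depression nodes); the fatigue scales hang off the physical
cluster with the Cognitive dimension uncovered; PSQI is isolated. The
greedy order is then SF-36, HAD, SCL 90 R, FIS8, FIS40, PSQI.

**What the generator does *not* emulate.** Real answer marginals are skewed,
not uniform; real subscales have heterogeneous loadings and item wording
effects; real missingness is informative (sicker patients complete more
forms), not Bernoulli; and real inter-instrument correlations are not
exhausted by eleven subject traits. Passing tests on these cohorts
demonstrates that the pipeline recovers planted structure and preserves
marginal distributions under its own generative assumptions — not that the
cascade attains any particular accuracy on hospital data. Held-out
per-answer accuracies on uniform-marginal synthetic cohorts (roughly
0.26–0.43 across steps at n = 2000) sit far below the 0.67–0.81 reported on
real registers, where skewed answer distributions make many items easy to
predict and evaluation used the training registers.

## Numerical choices

* Correlations: pairwise-complete observations (register counts differ per
  instrument; complete-case would discard most records); pairs with < 3
  complete records or zero variance are treated as no-edge with a warning.
* Multinomial backend: features standardized (constant columns get scale 1);
  zero initialisation; fixed iteration count rather than a convergence test,
  so training cost is predictable and results are exactly reproducible;
  class weights normalised to mean 1 so the learning rate is
  imbalance-invariant.
* Argmax ties broken toward the first (lowest) label; sampling uses one
  uniform draw per record against the cumulative score vector.
* Rounding in the regressor backend is half-away-from-zero (2.5 → 3), not
  banker's rounding, then clamped to the answer rank.
* Seeds: every stochastic operation takes an explicit seed; per-question
  sub-seeds are derived by a deterministic integer stream (all below 2^31),
  and RNG state is restored afterwards so callers' randomness is untouched.
* Validation split for early stopping: 20% stratified by label, at least one
  record per observed label kept in training.
* Degenerate inputs: single-class targets → constant predictor with
  warning; < 30 training records → error; zero real answer mass → mean
  error undefined (NA with warning); identical sum series → p = 1.

## Design decisions in open areas

* The ordering rule's source set is the union of already-selected
  questionnaires (matching what the cascade actually concatenates), not just
  the last one.
* 186 question models are trained — the item counts fix this number even
  though a count of 188 circulates in one summary table.
* Training inputs for steps ≥ 2 default to synthetic prior blocks;
  teacher forcing is exposed for study.
* Evaluation treats the sum-series statistic as a p-value; a paired-test
  switch is provided.
* PSQI is carried as 34 answer columns with 7 components plus a total, as
  printed in the source battery description, although the standard
  instrument is usually scored differently.

## Problem sizes used

Tests and the acceptance script run the full pipeline at 2000 training and
1000 held-out records with the multinomial backend — large enough for
stable correlation graphs (sampling error of r ≈ 0.02) and marginal
comparisons, small enough to keep the whole suite to a few minutes. The
null-calibration of the sum-series test uses 400 seeded replicates of
120-vs-120 record halves; the planted-graph recovery check uses an
independent 30,000-record oracle simulation to define the planted edge set.

## Limitations

* Sum-score subscales, not the instruments' norm-based scoring (PCS/MCS are
  plain sums of their halves).
* The bundled item-to-subscale map is structural, not the licensed key.
* No privacy guarantee is claimed or implemented (no differential privacy);
  the generator's safety argument is that classifiers trained on synthetic
  priors never memorise target records verbatim, which is weaker.
* Hyperparameter search is out of scope; the shipped per-step network
  configurations are fixed.
* The synthetic-cohort generator is a testing fixture calibrated to a
  qualitative narrative, not a clinical simulator of ME/CFS response
  distributions.
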