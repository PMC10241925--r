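---
title: "Learning small Boolean rule models for clinical phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning small Boolean rule models for clinical phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolfeat)
```

## The problem

Computable phenotypes — deterministic rules over electronic health record
(EHR) data that label patients for a condition — are usually either written
by hand (accurate, interpretable, expensive to curate) or learned by
black-box classifiers (cheap to train, impossible for a clinician to audit).
`boolfeat` targets the middle ground: it *learns* a phenotyping model whose
entire decision surface can be printed on a few lines, e.g.

```
"# enc 3+ meds, sum" > 1        +2.26
"# BP meds, max" > 2.5          +1.18
"Potassium, min" < 3.85         +0.95
...
```

Each line is a thresholded Boolean feature in raw clinical units entering a
logistic model. The motivating application is flagging apparent
treatment-resistant hypertension (aTRH) — persistently elevated blood
pressure despite three or more antihypertensive classes, or treatment with
four or more — as a trigger for primary-aldosteronism screening, where the
model's recommendation must be explainable at the point of care.

## The model

Given $N$ subjects with features $x \in \mathbb{R}^d$ and binary labels
$y \in \{0,1\}$, the fitted object is

$$\mathrm{logit}\, P(y = 1 \mid x) = \beta^T \Phi(x),$$

where $\Phi(x)$ is a learned $p$-dimensional representation: an ordered list
of expression trees over the operator set $\{<, >, \mathrm{AND},
\mathrm{OR}, \mathrm{NOT}\}$, plus bare feature leaves. Comparisons are
leaf-level — a tree compares a *raw input column* against a learned constant
— so every threshold in a printed model is in the feature's native units.
Comparison thresholds are learned by minimizing weighted Gini impurity over
the midpoints of consecutive observed values, as in CART, but unlike a
greedy tree learner the surrounding search can revisit and recombine
thresholded features, so globally useful cuts can surface that a greedy
split sequence would miss.

The representation and coefficients are optimized jointly against two
objectives, both minimized:

1. the **balanced logistic loss** on the training split — cross-entropy with
   class weights $N/(2N_c)$, so the minority class carries half the total
   weight regardless of prevalence; and
2. the **complexity** of $\Phi$ — a recursively weighted node count in which
   an operator node costs $w_{op}(1 + \sum_{\text{children}} c)$ and a leaf
   costs $w_{\mathrm{FEATURE}}$.

## The search

Each generation of the evolutionary loop:

* **selects** parents by epsilon-lexicase selection on the per-case balanced
  losses of each candidate's fitted model. Cases are shuffled and candidates
  filtered case by case, keeping those within $\varepsilon$ of the case
  elite, where $\varepsilon$ is the median absolute deviation of that case's
  losses over the surviving pool (configurable to strict zero). This
  preserves specialists for rare or difficult subjects, which matters at the
  ~10% outcome prevalence typical of phenotyping work;
* **varies** parents by insertion, deletion, point mutation (operator swaps,
  threshold re-learning or stepping to adjacent Gini candidates, feature
  resampling), subtree crossover, and a correlation-deletion operator that
  removes the member of the most inter-correlated derived-feature pair less
  correlated with the outcome;
* refits the logistic layer of each offspring by damped Newton iteration
  with a small ridge penalty (`1e-6`), which keeps coefficients finite when
  a Boolean column separates a fold; and
* applies NSGA-II **survival**: fast non-dominated sorting on (training
  loss, complexity), the final partial front ordered by crowding distance.

A cumulative **Pareto archive** retains every non-dominated candidate seen.
After the final generation the archived models are simplified (below) and
the model with the lowest balanced log-loss on the internal validation split
— a stratified 20% of the input, drawn once per run from the run seed — is
selected.

### Initialization

Input columns are ranked by the absolute coefficient of a standardized
univariate balanced logistic fit; sampling is proportional to these
magnitudes. Half the initial population are "linear seeds" (1 to `max_dim`
bare feature leaves), half are random typed trees with Gini-learned
thresholds. This biases the search toward informative low-dimensional
linear models without seeding a full multivariate fit, which would defeat
the purpose of learning a low-dimensional representation of
high-dimensional data.

### Simplification

Genetic programming bloats. Three post-run passes shrink the archive's
models while bounding the change in their predictions:

1. exact rewrites: `NOT(NOT(a)) -> a`, duplicate operands of `AND`/`OR`
   chains collapsed — prediction-preserving by construction;
2. iterated correlation deletion — accepted outright when the pruned pair is
   perfectly correlated ($|r| = 1$ within `1e-12`), otherwise only if the
   refit model's mean absolute change in predicted probability *relative to
   the pre-simplification model* stays within the tolerance;
3. iterated uniform subtree deletion — an internal subtree is replaced by a
   type-correct leaf drawn from inside it, accepted under the same
   cumulative-drift rule, with a proposal budget of five times the model
   size.

The drift is always measured against the original model, so accepted steps
cannot accumulate beyond the tolerance (default `0.005` mean absolute
probability). At tolerance zero only the exact passes act, which also makes
simplification idempotent there.

### Robust selection and thresholding

Because the search is stochastic, `fit_feat(..., n_restarts = 10)` reruns it
with reshuffled seeds (each restart re-draws its internal split), drops
restarts below the 25th percentile (linear interpolation) of validation
average precision, and returns the smallest surviving model. For deployment,
`choose_threshold()` scans all score cut-points on the combined training and
validation subjects and returns the most sensitive cut whose
prevalence-adjusted PPV,
$\mathrm{PPV} = se\,\rho / (se\,\rho + (1 - sp)(1 - \rho))$, meets the
target (default 0.70 at an assumed deployment prevalence, e.g. 7.5% for
aTRH in primary care).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pop_size` | 100 | candidates per generation |
| `generations` | 100 | search length |
| `max_dim` | 10 | derived features per model; 1 reduces the method to a single-rule learner |
| `max_depth` | 3 | tree depth (a leaf counts 1); depth 3 already expresses `A AND (B OR NOT C)` |
| variation rates | .2/.2/.3/.2/.1 | insertion / deletion / point / crossover / correlation-deletion |
| `ridge` | 1e-6 | logistic penalty; only meaningful against separation |
| `simplify_tolerance` | 0.005 | mean probability drift allowed in post-run simplification |
| `validation_frac` | 0.20 | internal held-out fraction |
| operator weights | FEATURE 1, NOT 1, comparisons/AND/OR 2, arithmetic 3 | complexity cost table |

Model **size** (reported alongside complexity) counts split nodes plus
leaves: a comparison contributes 2, a logical operator 1, a bare feature 1.
The six-line aTRH model above — five thresholded features plus one raw
feature — has size $5 \times 2 + 1 = 11$.

## Numerical choices

* Probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ before logs so a
  single confident error cannot contribute an infinite per-case loss to
  lexicase.
* The Newton fit declares convergence at a loss change below `1e-8` or 100
  iterations (25 inside the evolutionary loop, where only the candidate
  *ranking* matters and separable Boolean columns otherwise crawl along a
  ridge-dominated direction).
* Gini threshold ties resolve to the smallest midpoint; `>` and `<` are
  strict, so serialized models are unambiguous.
* `select_final` ties resolve by size, then complexity, then archive order.
* All randomness in a run flows from the single config seed; identical
  seed and data reproduce the archive, history, and selected model exactly.

## The synthetic cohorts

Two generators make every stage testable without access to protected
clinical data:

* `make_planted_rule()` draws Gaussian features (optionally in
  equicorrelated blocks) and labels them with a known Boolean rule plus
  optional label noise; thresholds can be bisection-tuned to a target
  prevalence. A noise-free dataset is perfectly classified by its own rule,
  which gates every recovery experiment.
* `make_ehr_like()` simulates latent primary-care trajectories — encounter
  days, a ratcheting count of antihypertensive classes, blood pressures
  responding to severity and treatment, labs, exclusion diagnoses — then
  emits only the summarized feature table (~330 columns of per-tier
  encounter counts, BP summaries, lab quantiles, diagnosis-code counts, note
  mentions). Labels come from the aTRH-style heuristic applied to the
  *latent* trajectories: two elevated pressures within five consecutive
  encounters on 30+ days of triple therapy, or four classes sustained 30
  days, censored by prior heart-failure/CKD exclusions. Because the labeler
  never sees the summarized columns, features relate to the outcome only
  statistically — mimicking the gap between chart review and extracted
  features. Prevalence lands near 10%.

What these generators do **not** emulate: real missingness mechanisms,
coding drift across sites, correlated measurement error, or free-text
evidence. Passing recovery tests therefore demonstrates that the search
machinery works, not that any particular clinical performance level
transfers to real EHR data. One consequence worth knowing: because each
planted dataset is labeled by a *single* Boolean rule, the ground truth
lies inside the 1-dimensional model class, so the discrimination advantage
of the multi-dimensional search over the `max_dim = 1` variant is small on
this suite — the advantage the method shows on real multi-factor tasks
comes from combining several partial rules additively, which single-rule
synthetic data cannot reward by construction.

## Problem sizes used in the checks

The bundled tests and the acceptance script run at desk scale, chosen to
exercise every code path while completing in minutes: rule recovery at
$n = 2000$, $d = 20$ with population 100 for 50 generations; the variant
ablation on five planted-rule datasets at $n = 600$ with population 50 for
25 generations and two 75/25 trials; the EHR-like pipeline at $n = 1200$,
$d \approx 330$ with population 50 for 15 generations. The cross-validation and ablation harnesses accept the full
paper-scale settings (50 repeats of 5-fold CV; 10 trials) unchanged.

## Design decisions that were genuinely open

* *Stratified internal split.* Stratification by label reduces the variance
  of validation losses at 10% prevalence; unstratified 80/20 splits can
  otherwise leave a handful of positives in validation.
* *Balanced weights as $N/(2N_c)$.* "Balanced" is operationalized as
  inverse-prevalence weighting, the standard convention; it is exposed in
  the API rather than hard-coded into the loss.
* *Pre-split median imputation.* Medians are computed on the full table
  before the internal split, matching pipelines that preprocess once per
  cohort; this leaks a small amount of validation information into training
  and is documented on `preprocess()`.
* *Thresholds learned at node creation.* Re-learning every threshold each
  generation would cost a full Gini scan per comparison per generation;
  instead thresholds are set when a comparison is created and revisited only
  by the threshold point-mutation, which steps to adjacent Gini candidate
  midpoints. Global exploration of cuts happens across the population
  rather than within each candidate.
* *Cumulative archive.* The archive accumulates non-dominated candidates
  over the whole run rather than per generation, giving model selection a
  dense complexity–loss front to choose from.
* *Per-case lexicase losses.* The case metric is each candidate's
  balanced-weighted per-sample cross-entropy under its own fitted
  coefficients.
* *Variance filter before imputation.* Filtering on observed-value variance
  avoids the imputation step manufacturing variance exactly at the filter
  boundary.
* *Ten restarts differ in both seed and split.* Reshuffling the internal
  split across restarts makes the robust-selection quartile a check on
  split sensitivity as well as seed sensitivity.

## Known limitations

* The arithmetic operator set exists only for ablation comparisons; the
  package does not try to be a general symbolic-regression engine.
* Adaptive pruning of representation components *during* the run (as
  opposed to the correlation-deletion mutation and post-run simplification)
  is not implemented.
* With `max_depth` 3 and leaf-level comparisons, rules requiring comparisons
  between two raw features (e.g. `SBP > DBP + 40`) are not expressible.
* The logistic layer is the only calibration; no isotonic or Platt
  recalibration is provided.
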