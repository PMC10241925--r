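# boolfeat

Interpretable Boolean feature learning for clinical phenotyping.

`boolfeat` learns classification models whose entire decision surface reads
as a handful of thresholded clinical rules. It is built for computable
phenotyping from summarized EHR feature tables — for example, flagging
apparent treatment-resistant hypertension (aTRH) as a trigger for
primary-aldosteronism screening — where a clinician must be able to audit
every part of the model, and for any tabular binary-outcome problem where
a six-line model beats an uninspectable one.

## The method

The fitted object is a logistic model on a *learned* feature representation:

    logit P(y = 1 | x) = β' Φ(x)

where Φ(x) is an ordered list of p expression trees over the Boolean
operator set {<, >, AND, OR, NOT} plus raw-feature leaves. Comparisons are
leaf-level (`feature > θ`, threshold learned by Gini impurity as in CART),
so printed models stay in native clinical units. Representations evolve by
genetic programming — epsilon-lexicase parent selection on per-case balanced
losses, insertion/deletion/point/crossover/correlation-deletion variation,
and NSGA-II survival on the two minimized objectives (balanced logistic
loss, representation complexity). A cumulative Pareto archive collects every
non-dominated candidate; after the run the archived models are simplified
(exact rewrites, correlation pruning, uniform subtree deletion, all within a
mean prediction-drift tolerance) and the model with the lowest balanced
log-loss on an internal 20% validation split is selected. A robust mode
reruns the search 10 times, drops the lowest validation-AUPRC quartile, and
keeps the smallest survivor. Decision thresholds can be calibrated to a
target prevalence-adjusted PPV.

See the methods vignette (`vignettes/boolean-feature-learning.Rmd`) for the
full model, parameter and design documentation.

## Worked example

```r
library(boolfeat)

# a synthetic cohort with a planted ground-truth rule: y = 1[x1 > 0.5 AND x2 > -0.3]
gen <- make_planted_rule(synthetic_spec(
  n = 1000, d = 10,
  rule = node_and(node_gt(1, 0.5), node_gt(2, -0.3)),
  label_noise = 0, seed = 42))
ds <- gen$dataset

cfg <- evolution_config(pop_size = 60, generations = 30, seed = 1)
fit <- feat_run(ds, cfg)

val <- predict_proba(fit$model, ds)
cat(model_report(fit$model), sep = "\n")
```

This run (about half a minute) prints:

```
(x2 < -0.2989 OR x1 < 0.4997)                                 -20.2303
(intercept)                                                   +10.1151
decision threshold: 0.5000
```

The search recovered the planted rule in De Morgan form — a subject is
scored low exactly when `x2 < -0.3 OR x1 < 0.5`, i.e. when the planted AND
fails — with both learned thresholds within 0.001 of the planted cuts.
Validation AUROC is 1.000, model size 5 (one OR node plus two comparisons,
each a split node and a feature leaf), and the Pareto archive holds 59
non-dominated models that can be inspected with `fit$archive` or exported
via `write_archive()`.

An EHR-flavoured end-to-end run:

```r
cohort <- preprocess(make_ehr_like(n = 1200, seed = 1))   # ~330 summarized columns, ~11% prevalence
model  <- fit_feat(cohort, evolution_config(pop_size = 50, generations = 15, seed = 1))
print(model)
```

## Command line

A thin launcher is installed at `inst/cli/boolfeat`:

```sh
boolfeat fit --data cohort.csv --label atrh --seed 1 --out run/
boolfeat predict --model run/model.json --data new_cohort.csv --out scores.csv
boolfeat report --model run/model.json
boolfeat benchmark --suite ablation --out bench/
```

`fit` writes `model.json` (bit-exact round-trip), `archive.json`, and
`history.csv`; flags override an optional `--config cfg.yaml`.

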