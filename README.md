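# foresiin

Forecasting one-year ischemic-stroke risk after a first atrial-fibrillation
(AF) episode, from two years of irregular electronic-health-record history —
with a model whose every prediction decomposes exactly into additive
per-feature effects.

## The problem and the model

Guideline stroke-risk scores for AF patients (CHA₂DS₂-VASc, ATRIA) use a
handful of baseline flags. An EHR holds far more: dozens of labs, vitals and
echocardiographic measures, observed irregularly and mostly missing. This
package implements **ForeSIIN** (Forecasting Strokes via Interpretable
Independent Networks): the two years before the first AF event are
summarized into 24 monthly records of m = 40 features (means for numeric,
modes for categorical features), remaining missing cells are either imputed
with training-set means/modes or — the primary, imputation-free setting —
replaced by a sentinel −1, and **one independent GRU per feature** consumes
its own monthly series. Branch `j`'s final hidden state passes through its
own small head to a scalar `u_j`, and the risk logit is the additive
combination

```
z = b + Σ_j  w_j u_j ,        score = σ(z) ,        e_j = w_j u_j
```

so `e_j` — the *perceptual feature effect* — is feature `j`'s exact additive
contribution to the prediction. Branches share no parameters (noise in one
feature cannot contaminate another's representation) and communicate only
through a composite loss that also trains each `σ(u_j)` as a sub-classifier
of the same label. The surrounding protocol is included: stratified 60/40
split with a 20% validation subset, 4:1 down-sampling of training negatives,
early stopping, decision thresholds (0.5 / Youden / F1 on validation),
1,000-resample bootstrap CIs, Harrell's c, Kaplan–Meier + log-rank by
predicted risk group, decision curves, classic ML benchmarks (LR, SVM, RF,
XGBoost, pooled GRU) and the two clinical comparator scores.

The study cohorts are not public, so the package ships a synthetic cohort
generator that emulates their structure — 40 mixed-type features with ~71%
monthly missingness, 8.6% one-year stroke prevalence driven by five planted
signals (history of TIA/stroke, eGFR, hsCRP, hematocrit, fasting glucose) —
with recorded ground truth for recovery testing. The recurrent core
(batched GRU forward/backward, composite loss, Adam) is implemented in
Rcpp/RcppArmadillo and its gradients are verified against finite differences
in the test suite.

## Worked example

```r
library(foresiin)

schema <- default_schema()                       # the 40-feature AF panel
cohort <- generate_cohort(sim_config(n_patients = 4000, seed = 1), schema)
labels <- make_label(cohort$timelines)           # stroke within 365 d of AF

sc    <- summarize_sequence(build_window(cohort$visits), schema,
                            cohort$timelines$patient_id)
split <- split_cohort(labels, seed = 1)
stats <- fit_train_statistics(sc, sc$patient_ids[c(split$train, split$validation)])
scd   <- scale_and_impute(sc, stats, "sentinel") # imputation-free -1 cells
ds    <- downsample_train(split, labels, 4)      # 4:1 negatives:positives

cfg <- model_config("independent", seed = 1)
fit <- train_model(init_params(cfg, 40),
                   scd$values[ds, , ], labels[ds],
                   scd$values[split$validation, , ], labels[split$validation])

test <- forward(fit$params, scd$values[split$test, , ])
roc_auc(test$score, labels[split$test])
#> [1] 0.8035172
rank_features(group_impact(test, labels[split$test]), 5)$feature
#> [1] "egfr"  "history_tia_is"  "fasting_glucose"  "hscrp"  "hematocrit"
```

The AUROC says the model separates stroke from stroke-free patients well
above chance on the held-out test set (the planted cohort's best achievable
value is ~0.85); the impact ranking — the mean difference in each feature's
additive effect between patients with and without a stroke — recovers all
five planted risk factors in the top five. A pooled GRU on the same tensors
reaches only ~0.55 here: with most cells missing, keeping features in
independent branches is what preserves the signal.

`inst/cli/foresiin` exposes the same pipeline as a command line
(`simulate | preprocess | train | evaluate | explain | benchmark | all`)
driven by a YAML config with full provenance written next to every output.

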