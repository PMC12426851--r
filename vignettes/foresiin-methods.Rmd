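---
title: "Interpretable independent recurrent networks for 1-year stroke risk after atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable independent recurrent networks for 1-year stroke risk after atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Patients with atrial fibrillation (AF) face an elevated risk of ischemic
stroke, and the point-based scores used in anticoagulation guidelines
(CHA2DS2-VASc, ATRIA) summarize only a snapshot of a patient's state. An
electronic health record, by contrast, holds two years of irregular visit
history before the first AF episode — dozens of labs, vitals and
echocardiographic measures, most of them missing at any given visit.
`foresiin` implements a forecaster for the binary outcome *first TIA or
ischemic stroke within one year of the first AF event* that consumes that
history directly, together with the full study protocol around it:
summarization, imputation policies, stratified splitting and down-sampling,
threshold selection, bootstrap confidence intervals, survival evaluation and
classic machine-learning benchmarks.

## Model

The input for one patient is a sequence of `T = 24` monthly records of
`m = 40` features. The model (the "independent" variant) runs one GRU with
scalar input and hidden size `h` per feature, so feature `j`'s branch sees
only its own monthly series. The final hidden state of branch `j` passes
through a small fully connected head (one hidden layer of width `k`, tanh
activation) to a scalar branch output `u_j`, and the prediction is the
additive combination

    z = b + sum_j w_j u_j,        score = sigmoid(z).

The products `e_j = w_j u_j` are the *perceptual feature effects*: they sum
to the logit exactly (machine precision; the test suite enforces 1e-5 over
random models and inputs), so every individual prediction decomposes into
one additive contribution per feature plus a shared bias. Because branches
share no parameters, perturbing feature `k`'s input changes `e_k` and
nothing else — this branch isolation is what blocks noise from leaking
between features when most cells are missing.

Two reference architectures are included: a conventional pooled GRU over the
full 40-dimensional input (`pooled_gru`) and per-feature GRUs feeding one
shared head (`shared_head`). Neither admits the additive decomposition.

### Composite loss

Branches communicate only through the loss,

    L = BCE(sigmoid(z), y) + lambda * mean_j BCE(sigmoid(u_j), y).

Each branch output is treated as a standalone sub-classifier of the same
label. We deliberately attach the per-branch term to `u_j` rather than to
the effect `e_j = w_j u_j`: with the combining weights initialized small (as
they must be, so the initial prediction is near 0.5), a branch term on `e_j`
multiplies every branch gradient by `w_j` and the optimizer spends tens of
epochs trapped near the symmetric initialization — in our experiments the
full model then plateaus near chance-level discrimination. With the branch
term on `u_j`, every sub-network receives a direct, label-anchored gradient
from the first step, the plateau disappears, and the combining weights are
free to learn *how much* (and with which sign) each trained branch
contributes. `lambda = 1` by default (selected on validation AUROC, see
below); `lambda = 0` recovers plain cross-entropy on the combined logit.

### Training

Mini-batch Adam (batch 64, learning rate 0.01, beta 0.9/0.999) with early
stopping: training halts when the validation loss has not improved for
`patience = 25` epochs (maximum 150) and the parameters of the best
validation epoch are returned. The monitored quantity is the validation
cross-entropy of the *combined prediction*, not the full composite loss:
the 40 per-branch terms are calibrated to the down-sampled 20% training
prior, so on the ~9%-prevalence validation split their growing
miscalibration would mask genuine improvements in the prediction and stop
training inside its initial plateau. The long patience is likewise
intentional — with a few hundred validation patients the per-epoch loss is
noisy. The independent variant additionally trains two restarts from
different initializations and keeps the one with the better validation
loss, guarding against initializations that strand the optimizer in the
plateau. All gradients are exact backpropagation-through-time, implemented
in compiled code and verified against central finite differences in the
test suite.

Every run is fully seeded. One user-facing seed drives several stages
(simulation, splitting, down-sampling, initialization, batch order), and
each stage derives its own scrambled sub-seed: re-seeding every stage with
the same integer would replay the same pseudo-random stream — the
stratified split, for instance, would then consume the very uniforms that
generated the cohort's feature latents, silently coupling split membership
to feature values.

Defaults `h = 8`, `k = 8` keep the 40-branch model at ~13k parameters,
comfortably CPU-trainable; the pooled baseline uses `h = 32`, `k = 16` for
a comparable budget. These defaults, the learning rate and `lambda` were
chosen on the *validation* split of a default synthetic cohort — never on
test data.

## Preprocessing conventions

* **Window and intervals.** Fixed 30-day intervals counted back from the
  first AF day: the window is days −719…0 and interval 24 (`[-29, 0]`)
  contains the AF event itself. Fixed width keeps `T = 24` exact; no
  calendar-month logic.
* **Summaries.** Numeric cells take the mean of the month's observations,
  binary/categorical cells the mode, with ties broken toward the smallest
  code (deterministic and order-independent).
* **Scaling.** Numeric features are min–max scaled to `[0, 1]` using
  training-split statistics only, clipping test values outside the training
  range; categorical codes are divided by the maximum training code. A
  degenerate feature (`min == max`) maps to 0.5. Scaling before sentinel
  substitution guarantees the sentinel is strictly outside the observed
  range.
* **Missing cells.** Two policies: `train_mean_mode` (scaled training
  mean/mode) and the default imputation-free `sentinel` (−1), which lets the
  model distinguish absence from any observed value without distributional
  assumptions.
* **Labels.** 1 iff the first TIA/ischemic stroke falls within 365 days of
  the first AF event. Patients censored earlier without an event are labeled
  0 — no patient is excluded, and an empty feature window yields an
  all-missing sequence rather than an exclusion.
* **Splits.** Stratified 60/40 train/test, then a stratified 20% of the
  training set as validation (fractions exact to one patient per stratum),
  then negatives down-sampled to 4:1 against positives in the remaining
  training set. Down-sampling removes negatives (keeping all positives is
  the only way to reach 4:1 from ~9% prevalence).

## Evaluation

AUROC (rank/trapezoidal, equal to pair concordance), AUPRC (step
interpolation; a random scorer scores the prevalence), Youden index and F1
at a threshold chosen on the validation split (`fixed` 0.5, `youden_max`,
or `f1_max`; candidates are midpoints between consecutive sorted scores
plus 0 and 1, ties to the smallest), recall/precision/G-mean from the same
confusion matrix, and Harrell's c on time-to-event data (standard
comparability rules; score ties count one half). Confidence intervals are
percentile bootstrap over patients with `B = 1000` replicates by default;
degenerate resamples are skipped and counted, and more than 50% of them is
an error. Kaplan–Meier curves and the two-group log-rank test delegate to
the survival package; risk groups for the KM analysis use the
validation-selected threshold, and follow-up is not truncated at 365 days.
Decision curves report `NB(p_t) = TP/n − (FP/n)·p_t/(1−p_t)` against
treat-all and treat-none references. Percentile (not BCa) intervals are the
simplest method consistent with a 1,000-resample protocol.

Feature impacts average the effects `e_j` on the independent test set within
the stroke (`t1`) and no-stroke (`t0`) groups; the ranking statistic is
`|t1 − t0|`. Averaging happens on the logit scale — forced by the additive
definition — and uses point estimates rather than bootstrap averages.
Because the bias cancels, `mean(z|t1) − mean(z|t0)` equals the sum of the
per-feature differences, a consistency the tests check to 1e-6.

## The synthetic cohort generator

The study cohorts are not public, so the generator builds cohorts with the
statistical structure the pipeline assumes, with recorded ground truth:

* 40 features (33 numeric labs/vitals/echo, 5 binary comorbidity flags, 2
  ordinal categories) with feature-specific monthly missingness averaging
  ~71%, floored by the visit process at `exp(-visit_rate)`.
* Per-patient numeric latents `N(mean_j, sd_j)` with visit-level noise
  (35% of the between-patient SD); binary/categorical features are
  patient-constant.
* Homogeneous Poisson visit counts per month (0.8/month by default; empty
  months exercise the missing-month path), a guaranteed index visit on day
  0, and a few visits before day −719 to exercise the windowing boundary.
* Outcome from a logistic model on the standardized patient latents of five
  planted features — history of TIA/IS (+0.55), eGFR (−0.90), hsCRP
  (+0.75), hematocrit (−0.55), fasting glucose (+0.60) — with the intercept
  bisected so the mean event probability hits the 8.6% target within 0.002.
  These effect sizes give the latent risk a Bayes AUROC of ~0.85, i.e. a
  cohort on which a well-trained model can plausibly reach the
  0.75–0.80 range, chosen once and not revisited.
* Event days for positives uniform on (0, 365]; censoring for event-free
  patients at a 90-day minimum follow-up plus a geometric tail (mean 540
  days), so roughly 40% of negatives are censored before day 365 — the KM
  and c-index paths see realistic censoring.
* Missingness is MCAR per feature by default; an optional MAR mode ties the
  visit rate to the latent risk.

What it does **not** emulate: correlations between features (eGFR and
creatinine are drawn independently), trends or seasonality within the
2-year window, medication/anticoagulant dynamics, ICD-coded ascertainment,
or informative censoring. Passing recovery tests on these cohorts therefore
demonstrates that the pipeline recovers planted monotone signals under heavy
missingness — not that it would match the published performance on a real
EHR cohort.

## Numerical choices and edge cases

* BCE is computed on the logit scale with the stable
  `max(z,0) − yz + log1p(exp(−|z|))` form.
* Every GRU's update-gate bias initializes at +2.5 (chrono-style): a
  neutral gate halves the state's memory each step, so the final state —
  the only input to the head — would start blind to all but the last
  couple of months and training would stall in a long plateau.
* Mode ties take the smallest code; threshold ties the smallest candidate;
  impact-rank ties the smaller feature index.
* A feature never observed in training imputes to 0 after scaling (logged).
* Zero predicted positives give precision = F1 = 0.
* The permutation null for the no-signal control uses the *maximum*
  `|t1 − t0|` across features (500 label permutations, 95th percentile):
  comparing each feature to its own marginal percentile would flag ~2 of 40
  features by chance construction.
* Problem sizes in the shipped tests — n = 4000 cohorts for recovery runs,
  n ≤ 500 for unit-level checks, B reduced from 1000 only where the CI is
  itself under test — were chosen so the full suite exercises the real
  protocol at desk scale.

## Known limitations

The composite-loss form and branch head widths are interpretations (the
original description names the loss but does not write it); both are
configurable. Scores are uncalibrated by design — down-sampling shifts the
training prior, so the sigmoid outputs rank patients but do not estimate
absolute risk. The benchmark hyperparameter grids are small and documented
in `fit_flat_model`; they are not a faithful reproduction of any published
grid. 3-fold validation is available by re-running the pipeline under
different split seeds rather than as a dedicated command.
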