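---
title: "Auditing APACHE IVa mortality-prediction errors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing APACHE IVa mortality-prediction errors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apacheaudit)
```

## The problem

APACHE IVa turns demographics, diagnosis and first-24-hour physiology of an
ICU stay into an in-hospital mortality probability. Dichotomised at a cutoff
c, the score makes two kinds of per-patient errors:

* **Type I** (false positive): the score predicts death (probability > c)
  but the patient survives to discharge;
* **Type II** (false negative): the score predicts survival (probability
  &le; c) but the patient dies in hospital.

The two errors have different clinical consequences — a missed death (Type
II) may mean a patient received less scrutiny than they needed — and, as it
turns out, different early predictors. `apacheaudit` implements a pipeline
that labels both errors in a multi-hospital cohort and asks which variables
available in the first 24 h of the stay predict each of them.

Because the multi-institutional ICU databases this kind of audit runs on
are access-restricted, the package ships a synthetic cohort generator
shaped like the eICU Collaborative Research Database tables. Every stage of
the pipeline is exercised, and every statistical claim in the test suite is
made, on generated data with known ground truth.

## ARC: the score's own confidence

For patient $i$ with predicted mortality probability $p_i$ and cutoff $c$,
the APACHE Relative Confidence is

$$
\mathrm{ARC}_i =
\begin{cases}
\dfrac{c - p_i}{c} & p_i \le c,\\[1ex]
\dfrac{p_i - c}{1 - c} & p_i > c.
\end{cases}
$$

ARC is 0 at the cutoff, 1 at both ends of $[0,1]$, and piecewise linear: it
normalises the distance of the prediction from the decision boundary by the
largest distance available on that side. Equality at the cutoff is assigned
to the left branch, consistent with "predicted death" requiring a strictly
greater probability. On both real and generated cohorts, binned Type I and
Type II error rates fall monotonically as ARC grows, which is why ARC is
offered (optionally) as a predictor in the error models: it is a one-number
summary of how far out on a limb the score went.

Three cutoffs are audited by default: 0.10 (a conventional high-risk
threshold), 0.50 (a conventional midpoint), and a *calibrated* cutoff chosen
so the fraction of stays classified as deaths matches the cohort's observed
mortality rate. `calibrate_cutoff()` searches all distinct predicted
probabilities plus a 0.001-step lattice and breaks ties towards the smaller
cutoff.

## The synthetic cohort generator

Each stay carries a latent severity $s \sim N(0,1)$.

* **Death**: $\Pr(\text{death}) = \operatorname{logit}^{-1}(\alpha + 1.5 s
  + \text{planted effects})$, with $\alpha$ solved so the cohort mortality
  hits its target (default 9.9%).
* **Score**: the predicted probability is
  $\operatorname{logit}^{-1}(\alpha' + 1.5 s + \varepsilon)$,
  $\varepsilon \sim N(0, 0.5^2)$, with $\alpha'$ solved so that mean
  predicted mortality equals `overprediction_factor` times the target
  (default 1.207, matching a score that predicts ~12.0% against ~9.9%
  observed). The score therefore tracks true risk but systematically
  overshoots, which is what puts most hospitals below the identity
  diagonal in the observed-vs-predicted scatter.
* **Planted error predictors**: a planted effect enters the death model but
  is hidden from the score. A protective flag (default: vasopressor given
  in the first day, log-odds $-0.8$) rescues patients the score had given
  up on, creating Type I errors; a risk flag (default: COPD history,
  $+0.8$) kills patients the score cleared, creating Type II errors. The
  magnitude 0.8 was chosen once as a clinically strong association; it is
  what the selection-recovery tests look for.
* **Labs and vitals** are drawn around reference midpoints (shipped as an
  editable catalog, `lab_catalog()`) with lab-specific spreads and severity
  slopes, so the "worst value" direction is meaningful: severity drags
  albumin and pH down, lactate and creatinine up. Per-lab missingness
  follows the catalog (3% for creatinine up to 95% for amylase) and is
  independent of the outcome unless reconfigured.
* **Hospitals** get bed counts by size class; no hospital-level intercept
  is added by default (a random-intercept audit of this design finds
  negligible between-hospital variance once severity is accounted for),
  but `hospital_effect_sd` exists as a stress knob.
* Small fractions of stays are planted to violate each exclusion rule so
  the cascade always has work to do.

Randomness is organised as one master seed feeding named child streams
(hospitals, stays, history, care plan, treatments, diagnoses, outcome,
labs, periodic vitals, aperiodic vitals, exclusion plants, in that order),
so every table is reproducible bit for bit.

What the generator does **not** emulate: realistic physiologic time-series
dynamics, correlations between labs beyond the shared severity factor, the
real databases' exact column inventories, informative missingness, or
admission-diagnosis case mix tied to outcomes. Tests passing on this
cohort demonstrate that the pipeline recovers structure that is present by
construction; they say nothing about effect sizes in real ICU data.

## Cohort construction

`apply_exclusions()` applies, in order: no score prediction; no Glasgow
coma scale; lung/heart transplant or burns admissions; age under 16;
ICU readmissions or admissions from another ICU; no periodic vital records
("no" is read as *zero* periodic records — the minimum-coverage alternative
is not specified anywhere authoritative, and zero is the conservative
reading); restriction to the last ICU stay of the final hospital stay,
removing patients whose hospital-stay ordering is masked; and finally
missing care-plan, BMI or history records. The report reproduces a
flow-chart-style ledger for any input. `split_holdout()` then reserves a
random 20% (rounded to nearest, ties to even) for final validation; all
standardization, imputation fitting and penalty tuning happen on the
remaining 80%.

## Feature engineering

* **Worst lab values** follow per-lab direction rules: minimum (e.g.
  albumin, pH, platelets), maximum (e.g. lactate, creatinine, BUN),
  most-deviant-from-range (glucose, sodium; deviation is
  $\max(\text{low}-x,\ x-\text{high})$, ties to the higher value), and
  conditional minimum (WBC, neutrophils: minimum only if something fell
  below the lower limit, else maximum). A single measurement is its own
  worst value; no measurement is a missing cell for the imputation stage.
  Reference ranges are conventional adult values and deliberately live in
  an editable CSV, since no authoritative set is bundled with the source
  databases.
* **Vitals**: mean plus *both* extremes of each periodic vital. The worst
  direction of a vital is context-dependent (low SpO2 is bad; heart rate
  can be bad in either direction), so the package emits mean/min/max and
  lets the Lasso decide. The "mean aperiodic vital" is the mean of the
  first-24h aperiodic blood-pressure measurements — the value
  interpretation, rather than measurement frequency, is the assumption
  made here and it is flagged as such.
* **Diagnoses**: free text is matched against a keyword dictionary into 21
  categories; acute coronary syndrome is the baseline, so 20 indicator
  columns are produced and each row sums to 0 (ACS) or 1.
* **Standardization** to mean 0, variance 1 uses the sample SD (divisor
  $n-1$) estimated on training rows only and applied to all rows;
  zero-variance columns are dropped with a warning.

## Missing data

Only lab columns are imputed; the score itself is never imputed (stays
without a score are excluded — the score's weights are proprietary, so its
missingness is not recoverable). Three strategies, all fitted on the
training split and applied to the holdout, all leaving observed cells
untouched:

1. **Averaged multiple imputation** (`impute_multiple`): chained-equation
   stochastic regression with all lab and vital columns as predictors, 10
   sweeps, 10 completions; each missing cell gets the *mean of its 10
   imputed values*. Pooling completions into one dataset (rather than
   Rubin's rules over model fits) is a deliberate interpretation: the
   pipeline needs a single completed matrix before selection.
2. **Median fill with flags** (`impute_median_with_flags`): training-split
   median plus a `miss_*` indicator per lab with any missingness; the
   flags join the candidate feature set ("was this test even ordered?" is
   itself clinical signal).
3. **Severity-decile group means** (`impute_group_mean`): stays are ranked
   by APACHE score into 10 equal-sized groups (ties broken by stable row
   order); each hole takes its group's observed mean, falling back to the
   overall mean for empty groups.

## Modeling

Each error type is modelled *on its own prediction side*: the Type I model
is fit among stays the score classified as deaths (response: survived), the
Type II model among classified survivors (response: died). That is what
makes the published conditional error rates (roughly half of predicted
deaths survive; a few percent of predicted survivors die) the relevant
base rates, and it is why Type II modelling is a rare-event problem.

* **ADASYN** (`adasyn_oversample`): minority points are oversampled in
  proportion to the majority share among their k nearest neighbours;
  synthetic points are convex combinations of minority neighbours; the
  default target is full balance. It is applied inside each CV training
  fold and to the final training sample — never to validation or holdout
  data.
* **Penalty selection** (`fit_lasso_cv`): a 100-value log-spaced penalty
  path (four decades below the all-zero penalty) is tuned by stratified
  10-fold CV on binomial deviance. One subtlety matters: a fold model
  trained on rebalanced data carries the artificial ~50% base rate, and
  its raw validation deviance is dominated by that intercept shift, which
  pushes the apparent optimum to uselessly small penalties. The package
  therefore applies the standard prior correction — subtracting the
  artificial-vs-true base-rate log odds from the linear predictor — before
  scoring each validation fold. With calibrated deviances the CV curve
  flattens once real signal is captured and the one-SE rule behaves as
  intended. Two rules are available: **one-SE** (largest penalty within
  one standard error of the CV minimum; the default) and **CI-95**
  (largest penalty within the 95% CI of the minimum), which by
  construction never selects a smaller penalty, hence never a larger
  model. Which rule produced any given published table is generally not
  stated; both are first-class here.
* **Inference refit** (`refit_unpenalized`): ordinary logistic regression
  on the selected features, reporting coefficient, SE, absolute Z-ratio
  and Wald 95% CI, sorted by Z-ratio. The refit runs on the same
  ADASYN-augmented training sample as the final selection fit — the
  reported SEs describe that rebalanced sample (this is the only reading
  consistent with published SEs of ~0.008 on a ~5% prevalence outcome),
  so they should be read as descriptive of the pipeline, not as
  population inference. Complete separation falls back to a lightly
  ridge-stabilized Newton fit and is flagged.
* **Holdout evaluation**: the refit model's probabilities are thresholded
  at 0.5 (predictions come from a balanced-sample model, so 0.5 is the
  natural operating point); precision, recall, F-score, accuracy, AUROC
  (tie-corrected rank statistic) and AUPRC (step interpolation /
  average-precision convention) are reported, with the conditional error
  prevalence as context. For rare Type II errors, AUPRC and F-score are
  the metrics to watch — AUROC is inflated by the easy negatives.

## Numerical choices and degenerate inputs

* Calibration grid ties &rarr; smallest cutoff; "most deviant" ties &rarr;
  higher value; score-decile ties &rarr; stable row order.
* Empty measurement lists &rarr; missing markers; empty bins &rarr; `NA`
  rates; empty selected set &rarr; an error advising a laxer penalty rule.
* Zero-variance features are dropped before modeling, with a warning.
* Folds are stratified by class; a fold that still lacks a class is an
  error rather than a silent skip.

## Problem sizes

The package's reference experiments run at 20,000 generated stays (the
desk-scale stand-in for a ~90k-stay registry cohort), with 50,000 used for
the two calibration-shape properties (hospital scatter and ARC-binned
error curves) where per-hospital and per-bin counts need the head room.
Selection-recovery claims are made over 10 generator seeds; stability
claims over 5 reseeded replications of the CV/selection stage on one
cohort.

## Known limitations

* ADASYN interpolates binary indicators to fractional values; the refit's
  SEs on augmented samples are descriptive, not inferential.
* The multiple-imputation engine is Gaussian-linear; skewed labs are
  imputed on their natural scale, not log scale.
* The generator's severity is one-dimensional, so engineered features are
  more mutually correlated than real physiology; selection among them is
  correspondingly less determined than the planted-flag recoveries.
* A mixed-effects (hospital random-intercept) variant is deliberately not
  implemented; with the default generator there is no hospital effect to
  find, and the stress knob exists for users who want to add one.
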