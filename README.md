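# apacheaudit

Tools for auditing when the APACHE IVa severity-of-illness score gets
in-hospital mortality wrong, and for finding the first-24-hour variables
that predict those mistakes.

APACHE IVa maps the first 24 h of an ICU stay to a mortality probability.
Dichotomised at a cutoff *c*, the score makes two kinds of errors:

* **Type I** (false positive): predicted death (probability > *c*), patient
  survives to discharge;
* **Type II** (false negative): predicted survival, patient dies in
  hospital.

The package implements the full audit pipeline used to study these errors
in multi-hospital ICU cohorts:

* **ARC**, the APACHE Relative Confidence — the normalized distance of the
  prediction from the cutoff,

  ```
  ARC = (c − p) / c        if p ≤ c
        (p − c) / (1 − c)  if p > c
  ```

  which is 0 at the cutoff, 1 at both extremes, and empirically tracks how
  unlikely either error is;
* cutoff **calibration** so the share of predicted deaths matches observed
  mortality, alongside the conventional 0.10 and 0.50 cutoffs;
* the cohort **exclusion cascade** and 80/20 holdout split;
* first-24h **feature engineering**: worst lab values under per-lab
  direction rules (min, max, most-deviant-from-range, conditional-min),
  vital-sign mean/min/max, a 21-category admission-diagnosis grouping, and
  training-split standardization;
* three **missing-data strategies** for unperformed labs: averaged
  multiple imputation, median fill with test-not-performed flags, and
  severity-score decile group means;
* **ADASYN** minority oversampling, **Lasso-logistic** feature selection
  with 10-fold CV penalty choice (one-SE and 95%-CI rules), and an
  unpenalized logistic **refit** reporting coefficient / SE / |Z| / 95% CI;
* imbalance-aware **evaluation** (precision, recall, F-score, AUPRC,
  AUROC, accuracy) on the holdout, plus hospital-level
  observed-vs-predicted calibration summaries.

Because the ICU databases this audit targets are access-restricted, the
package ships a **synthetic cohort generator** shaped like the eICU
Collaborative Research Database tables: a latent-severity outcome model, a
deliberately overpredicting score, realistic per-lab missingness (3–95%),
and *planted* feature–error associations so every selection claim can be
validated by recovery. See the vignette
(`vignettes/auditing-severity-score-errors.Rmd`) for the models and all
design decisions.

## Worked example

```r
library(apacheaudit)

cfg  <- sim_config(n_stays = 8000, n_hospitals = 20, seed = 42)
tabs <- apply_exclusions(generate_cohort(cfg))$tables
st   <- tabs$stays

sp     <- split_holdout(st$stay_id, fraction = 0.2, seed = 1)
cutoff <- calibrate_cutoff(st$apache_prob[st$stay_id %in% sp$train],
                           mean(st$died[st$stay_id %in% sp$train]))
cutoff
#> <cutoff_spec> 0.3373 (calibrated): 9.73% classified as deaths vs 9.73% observed

labels <- label_errors(st$apache_prob, cutoff, st$died, stay_id = st$stay_id)
fm     <- build_feature_matrix(tabs)
imp    <- impute_median_with_flags(fm, fit_rows = which(fm$x$stay_id %in% sp$train))

fit <- fit_error_model(imp$features, labels, sp$train, sp$holdout,
                       model_config("type1", seed = 3))
fit$selection$selected
#> [1] "mean_spo2"   "min_spo2"    "vasopressor" "arc"
```

The calibrated cutoff lands where 9.73% of training stays are classified
as deaths — exactly the observed training mortality. The Type I model
(fit among stays the score classified as deaths, response = survived)
selects a handful of features: ARC with a negative coefficient (more
extreme predictions fail less), oxygen-saturation summaries, and the
vasopressor flag — the treatment this generator plants
as a Type I error predictor (patients rescued after the score had written
them off). The refit table in `fit$inference` carries coefficient, SE,
absolute Z-ratio and 95% CI per selected feature; `fit$metrics` holds the
holdout confusion counts, precision/recall/F, AUROC and AUPRC.

An experiment grid over cutoffs × imputation methods × responses × ARC
inclusion, with per-cell JSON artifacts and resume support, is one call:
`run_grid(run_spec(), tabs, out_dir = "runs")`. A thin CLI over the same
functions lives at `inst/cli/apacheaudit.R`
(`simulate` / `build` / `fit` / `run-all`).

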