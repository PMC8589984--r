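# Shared fixtures. Cohorts are generated in code and memoised per test run
# so expensive builds (n = 20,000) happen once per process.

.fixture_cache <- new.env(parent = emptyenv())

# full built cohort: tables after exclusions, split, features, calibrated
# cutoff and error labels
built_cohort <- function(n_stays, seed, config = NULL) {
  key <- paste0("cohort_", n_stays, "_", seed)
  if (!is.null(config)) key <- paste0(key, "_custom")
  if (!exists(key, .fixture_cache)) {
    cfg <- if (is.null(config)) sim_config(n_stays = n_stays, seed = seed) else config
    tabs <- apply_exclusions(generate_cohort(cfg))$tables
    st <- tabs$stays
    sp <- split_holdout(st$stay_id, 0.2, seed = seed)
    fm <- build_feature_matrix(tabs)
    train_rows <- which(fm$x$stay_id %in% sp$train)
    cutoff <- calibrate_cutoff(st$apache_prob[st$stay_id %in% sp$train],
                               mean(st$died[st$stay_id %in% sp$train]))
    labels <- label_errors(st$apache_prob, cutoff, st$died,
                           stay_id = st$stay_id)
    assign(key, list(config = cfg, tables = tabs, stays = st, split = sp,
                     features = fm, train_rows = train_rows,
                     cutoff = cutoff, labels = labels),
           .fixture_cache)
  }
  get(key, .fixture_cache)
}

# a raw feature_matrix built directly (bypassing the generator) for
# imputation unit tests
make_feature_matrix <- function(x, lab_cols,
                                vital_cols = setdiff(names(x),
                                                     c("stay_id", lab_cols))) {
  prov <- setNames(rep("lab", length(lab_cols)), lab_cols)
  prov[vital_cols] <- "vital_periodic"
  if (!"stay_id" %in% names(x)) x <- cbind(stay_id = seq_len(nrow(x)), x)
  structure(list(x = x, lab_cols = lab_cols, provenance = prov),
            class = "feature_matrix")
}

# hand-built raw_tables with explicit exclusion violations
tiny_tables <- function(stays, labs = NULL, vitals_stays = stays$stay_id) {
  n <- nrow(stays)
  defaults <- data.frame(
    stay_id = stays$stay_id,
    patient_id = stays$stay_id,
    hospital_id = 1L, beds = 120L,
    hospital_stay_order = 1L, unit_visit_number = 1L,
    unit_admit_source = "Emergency Department",
    age = 50, gender = "Female", bmi = 25, gcs = 14,
    admission_dx = "Sepsis, pulmonary",
    apache_score = 60, apache_prob = 0.2, died = 0L)
  for (cc in names(stays)) defaults[[cc]] <- stays[[cc]]
  if (is.null(labs)) {
    labs <- data.frame(stay_id = integer(0), lab = character(0),
                       offset_hours = numeric(0), value = numeric(0))
  }
  vp <- data.frame(stay_id = vitals_stays, offset_hours = 1,
                   heart_rate = 80, respiratory_rate = 18, spo2 = 97)
  va <- data.frame(stay_id = defaults$stay_id, offset_hours = 2, mean_bp = 85)
  structure(list(
    stays = defaults, labs = labs, vitals_periodic = vp,
    vitals_aperiodic = va,
    treatments = data.frame(stay_id = defaults$stay_id, vasopressor = 0L,
                            ventilated_day1 = 0L, lactate_test = 0L),
    careplan = data.frame(stay_id = defaults$stay_id, care_limitation = 0L),
    history = data.frame(stay_id = defaults$stay_id, hx_copd = 0L,
                         hx_diabetes = 0L, hx_chf = 0L, hx_renal = 0L,
                         hx_cancer = 0L)),
    class = "raw_tables")
}

# features drawn independently of severity and outcome in the generator;
# used to count spuriously selected features
null_feature_names <- function(features) {
  cols <- setdiff(names(features$x), "stay_id")
  cols[grepl("^dx_|^miss_", cols) |
         cols %in% c("hx_diabetes", "hx_chf", "hx_renal", "hx_cancer",
                     "bmi", "age")]
}
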