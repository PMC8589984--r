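# Synthetic multi-hospital cohort generator.
#
# Mechanism: each stay carries a latent severity s ~ N(0,1). True death risk
# is logistic(alpha + 1.5 s + hospital effect + planted effects); the
# severity score's predicted probability is logistic(alpha' + 1.5 s + noise)
# with alpha' solved so that mean predicted = overprediction_factor * target
# mortality. Planted effects enter the death model but not the score, so
# they predict the score's errors by construction. Labs and vitals are drawn
# around lab-specific reference midpoints with a severity slope, so worst
# values carry signal in the clinically expected direction.

dx_phrases <- function() {
  c(acs = "Acute coronary syndrome / myocardial infarction",
    arf = "Renal failure, acute",
    asthma_emphysema = "Asthma / emphysema exacerbation",
    cabg = "Coronary artery bypass graft, elective",
    cardiac_arrest = "Cardiac arrest, out of hospital",
    chest_pain = "Chest pain, rule out MI",
    chf = "Congestive heart failure, decompensated",
    coma = "Coma, unknown etiology",
    cva = "CVA, cerebrovascular accident/stroke",
    dka = "Diabetic ketoacidosis",
    gi_bleed = "Bleeding, upper GI",
    gi_obstruction = "GI obstruction, small bowel",
    neurologic = "Seizures, status epilepticus",
    overdose = "Overdose, sedatives/hypnotics",
    pneumonia = "Pneumonia, bacterial",
    sepsis = "Sepsis, pulmonary",
    trauma = "Trauma, multiple injury",
    valve_disease = "Valve replacement, aortic",
    other_cerebrovascular = "Subarachnoid hemorrhage",
    other_respiratory = "Respiratory failure, acute hypoxemic",
    other = "Rhabdomyolysis")
}

dx_weights <- function() {
  c(acs = 7, arf = 4, asthma_emphysema = 4, cabg = 5, cardiac_arrest = 4,
    chest_pain = 5, chf = 7, coma = 2, cva = 6, dka = 4, gi_bleed = 5,
    gi_obstruction = 2, neurologic = 5, overdose = 4, pneumonia = 7,
    sepsis = 9, trauma = 6, valve_disease = 3, other_cerebrovascular = 3,
    other_respiratory = 7, other = 6)
}

# solve intercept so mean(plogis(alpha + eta)) == target
solve_intercept <- function(eta, target) {
  uniroot(function(a) mean(plogis(a + eta)) - target,
          interval = c(-30, 30), tol = 1e-10)$root
}

#' Generate a synthetic eICU-shaped cohort
#'
#' Draws a multi-hospital cohort of ICU stays with a miscalibrated severity
#' score, first-24h labs/vitals/treatment/care-plan/history/diagnosis
#' tables, per-lab missingness, and planted feature-error associations.
#' Deterministic under the config's master seed: each table is drawn from
#' its own child stream (order: hospitals, stays, history, careplan,
#' treatments, diagnoses, outcome, labs, periodic vitals, aperiodic vitals,
#' exclusion plants), so the same config yields identical tables.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{raw_tables}: a list of data frames
#'   \code{stays}, \code{labs}, \code{vitals_periodic},
#'   \code{vitals_aperiodic}, \code{treatments}, \code{careplan},
#'   \code{history}.
#' @export
#' @examples
#' tabs <- generate_cohort(sim_config(n_stays = 300, n_hospitals = 5, seed = 7))
#' nrow(tabs$stays)
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  n <- config$n_stays
  seeds <- child_seeds(config$seed)
  catalog <- config$catalog

  ## hospitals -----------------------------------------------------------
  set.seed(seeds[["hospitals"]])
  nh <- config$n_hospitals
  size_class <- sample(c("very_small", "small", "medium", "large"), nh,
                       replace = TRUE, prob = config$hospital_size_weights)
  beds <- ifelse(size_class == "very_small", sample(30:99, nh, TRUE),
          ifelse(size_class == "small", sample(100:249, nh, TRUE),
          ifelse(size_class == "medium", sample(250:499, nh, TRUE),
                 sample(500:900, nh, TRUE))))
  hosp_re <- if (config$hospital_effect_sd > 0) {
    rnorm(nh, 0, config$hospital_effect_sd)
  } else rep(0, nh)

  ## stays: severity, demographics, stay structure -----------------------
  set.seed(seeds[["stays"]])
  s <- rnorm(n)
  hospital_idx <- sample.int(nh, n, replace = TRUE)
  age <- pmin(pmax(round(rnorm(n, 63, 16)), 16), 95)
  gender <- sample(c("Female", "Male"), n, replace = TRUE)
  bmi <- round(pmin(pmax(rnorm(n, 28, 6), 14), 60), 1)
  gcs <- pmin(pmax(round(15 - 2.2 * pmax(s, 0) - rpois(n, 0.5)), 3), 15)

  patient_id <- seq_len(n)
  hospital_stay_order <- rep(1L, n)
  unit_visit_number <- rep(1L, n)
  unit_admit_source <- rep("Emergency Department", n)

  ## history --------------------------------------------------------------
  set.seed(seeds[["history"]])
  history <- data.frame(
    stay_id = seq_len(n),
    hx_copd = rbinom(n, 1, 0.15),
    hx_diabetes = rbinom(n, 1, 0.25),
    hx_chf = rbinom(n, 1, 0.12),
    hx_renal = rbinom(n, 1, 0.08),
    hx_cancer = rbinom(n, 1, 0.10))

  ## care plan ------------------------------------------------------------
  set.seed(seeds[["careplan"]])
  careplan <- data.frame(
    stay_id = seq_len(n),
    care_limitation = rpois(n, exp(-1.5 + 0.5 * s)))

  ## treatments -----------------------------------------------------------
  set.seed(seeds[["treatments"]])
  treatments <- data.frame(
    stay_id = seq_len(n),
    vasopressor = rbinom(n, 1, plogis(-1.6 + 0.7 * s)),
    ventilated_day1 = rbinom(n, 1, plogis(-1.3 + 0.9 * s)),
    lactate_test = 0L)  # filled after lab draw

  ## admission diagnoses --------------------------------------------------
  set.seed(seeds[["dx"]])
  cats <- names(dx_weights())
  dx_cat <- sample(cats, n, replace = TRUE, prob = dx_weights())
  admission_dx <- unname(dx_phrases()[dx_cat])

  ## outcome and score ----------------------------------------------------
  set.seed(seeds[["outcome"]])
  planted <- rep(0, n)
  for (nm in names(config$planted_effects)) {
    pe <- config$planted_effects[[nm]]
    val <- switch(nm,
      vasopressor = treatments$vasopressor,
      ventilated_day1 = treatments$ventilated_day1,
      care_limitation = careplan$care_limitation,
      history[[nm]])
    delta <- if (pe$type == "type2") abs(pe$beta) else -abs(pe$beta)
    planted <- planted + delta * val
  }
  eta_true <- 1.5 * s + hosp_re[hospital_idx] + planted
  alpha <- solve_intercept(eta_true, config$target_observed_mortality)
  p_death <- plogis(alpha + eta_true)
  died <- rbinom(n, 1, p_death)

  eta_score <- 1.5 * s + rnorm(n, 0, config$prediction_noise_sd)
  target_pred <- config$overprediction_factor * config$target_observed_mortality
  alpha2 <- solve_intercept(eta_score, target_pred)
  apache_prob <- plogis(alpha2 + eta_score)
  apache_score <- pmin(pmax(round(45 + 23 * s + rnorm(n, 0, 7)), 10), 200)

  ## labs ------------------------------------------------------------------
  set.seed(seeds[["labs"]])
  lab_frames <- vector("list", nrow(catalog))
  lactate_present <- logical(n)
  for (i in seq_len(nrow(catalog))) {
    lab <- catalog$lab[i]
    present <- runif(n) >= config$lab_missingness[[lab]]
    if (lab == "lactate") lactate_present <- present
    idx <- which(present)
    if (!length(idx)) {
      lab_frames[[i]] <- data.frame(stay_id = integer(0), lab = character(0),
                                    offset_hours = numeric(0),
                                    value = numeric(0))
      next
    }
    n_meas <- 1L + rpois(length(idx), 1.2)
    rows <- rep(idx, n_meas)
    mu <- if (catalog$scale[i] == "log") {
      log(max(catalog$mid[i], 0.01)) + catalog$severity_slope[i] * s[rows]
    } else {
      catalog$mid[i] + catalog$severity_slope[i] * s[rows]
    }
    z <- rnorm(length(rows), 0, catalog$spread[i])
    value <- if (catalog$scale[i] == "log") exp(mu + z) else mu + z
    lab_frames[[i]] <- data.frame(
      stay_id = rows, lab = lab,
      offset_hours = round(runif(length(rows), 0, 24), 2),
      value = round(value, 4))
  }
  labs <- do.call(rbind, lab_frames)
  labs <- labs[order(labs$stay_id, labs$lab, labs$offset_hours), ]
  rownames(labs) <- NULL
  treatments$lactate_test <- as.integer(lactate_present)

  ## periodic vitals -------------------------------------------------------
  set.seed(seeds[["vitals_periodic"]])
  nobs <- sample(8:16, n, replace = TRUE)
  rows <- rep(seq_len(n), nobs)
  vitals_periodic <- data.frame(
    stay_id = rows,
    offset_hours = round(runif(length(rows), 0, 24), 2),
    heart_rate = round(85 + 12 * s[rows] + rnorm(length(rows), 0, 10), 1),
    respiratory_rate = round(pmax(18 + 3 * s[rows] +
                                  rnorm(length(rows), 0, 4), 4), 1),
    spo2 = round(pmin(pmax(97 - 2.5 * pmax(s[rows], 0) +
                           rnorm(length(rows), 0, 2), 60), 100), 1))
  vitals_periodic <- vitals_periodic[order(vitals_periodic$stay_id,
                                           vitals_periodic$offset_hours), ]
  rownames(vitals_periodic) <- NULL

  ## aperiodic vitals ------------------------------------------------------
  set.seed(seeds[["vitals_aperiodic"]])
  nobs_a <- 1L + rpois(n, 3)
  rows_a <- rep(seq_len(n), nobs_a)
  vitals_aperiodic <- data.frame(
    stay_id = rows_a,
    offset_hours = round(runif(length(rows_a), 0, 24), 2),
    mean_bp = round(85 - 6 * s[rows_a] + rnorm(length(rows_a), 0, 12), 1))
  vitals_aperiodic <- vitals_aperiodic[order(vitals_aperiodic$stay_id,
                                             vitals_aperiodic$offset_hours), ]
  rownames(vitals_aperiodic) <- NULL

  ## planted exclusion triggers -------------------------------------------
  set.seed(seeds[["exclusions"]])
  ef <- config$exclusion_fractions
  pick <- function(frac, avoid = integer(0)) {
    k <- round(frac * n)
    if (k == 0) return(integer(0))
    pool <- setdiff(seq_len(n), avoid)
    sample(pool, min(k, length(pool)))
  }
  i_apache <- pick(ef$missing_apache)
  apache_prob[i_apache] <- NA
  apache_score[i_apache] <- NA
  gcs[pick(ef$missing_gcs)] <- NA
  i_tb <- pick(ef$transplant_burn)
  admission_dx[i_tb] <- sample(c("s/p lung transplant", "s/p heart transplant",
                                 "Burns, severe"), length(i_tb), TRUE)
  dx_cat[i_tb] <- "other"
  i_young <- pick(ef$under_16)
  age[i_young] <- sample(8:15, length(i_young), TRUE)
  i_re <- pick(ef$readmission)
  if (length(i_re)) {
    half <- seq_len(length(i_re) %/% 2)
    unit_visit_number[i_re[half]] <- 2L
    unit_admit_source[i_re[-half]] <- "Other ICU"
  }
  i_nv <- pick(ef$no_vitals)
  if (length(i_nv)) {
    vitals_periodic <- vitals_periodic[!vitals_periodic$stay_id %in% i_nv, ]
  }
  # multi-hospital-stay pairs: row b is the later hospital stay of row a's
  # patient; unresolvable pairs have NA ordering on both rows
  used <- c(i_re)
  k_pair <- round(ef$multi_hospital_stay * n / 2)
  k_unres <- round(ef$unresolvable_order * n / 2)
  pool <- setdiff(seq_len(n), used)
  need <- 2 * (k_pair + k_unres)
  if (need > 0 && length(pool) >= need) {
    idx <- sample(pool, need)
    if (k_pair > 0) {
      a <- idx[seq_len(k_pair)]; b <- idx[k_pair + seq_len(k_pair)]
      patient_id[b] <- patient_id[a]
      hospital_stay_order[a] <- 1L
      hospital_stay_order[b] <- 2L
    }
    if (k_unres > 0) {
      off <- 2 * k_pair
      a <- idx[off + seq_len(k_unres)]
      b <- idx[off + k_unres + seq_len(k_unres)]
      patient_id[b] <- patient_id[a]
      hospital_stay_order[a] <- NA
      hospital_stay_order[b] <- NA
    }
  }
  bmi[pick(ef$missing_bmi)] <- NA
  i_nohx <- pick(ef$missing_history)
  if (length(i_nohx)) history <- history[-i_nohx, ]
  i_nocp <- pick(ef$missing_careplan)
  if (length(i_nocp)) careplan <- careplan[-i_nocp, ]

  stays <- data.frame(
    stay_id = seq_len(n),
    patient_id = patient_id,
    hospital_id = hospital_idx,
    beds = beds[hospital_idx],
    hospital_stay_order = hospital_stay_order,
    unit_visit_number = unit_visit_number,
    unit_admit_source = unit_admit_source,
    age = age, gender = gender, bmi = bmi, gcs = gcs,
    admission_dx = admission_dx,
    apache_score = apache_score,
    apache_prob = apache_prob,
    died = died)

  structure(list(stays = stays, labs = labs,
                 vitals_periodic = vitals_periodic,
                 vitals_aperiodic = vitals_aperiodic,
                 treatments = treatments, careplan = careplan,
                 history = history),
            class = "raw_tables",
            seed = config$seed)
}

#' @export
print.raw_tables <- function(x, ...) {
  cat("<raw_tables>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-17s %8d rows x %d cols\n", nm, nrow(x[[nm]]),
                ncol(x[[nm]])))
  }
  invisible(x)
}

raw_table_files <- c(
  stays_patient = "patient.csv",
  stays_apache = "apachePatientResult.csv",
  stays_dx = "admissionDx.csv",
  labs = "lab.csv",
  vitals_periodic = "vitalPeriodic.csv",
  vitals_aperiodic = "vitalAperiodic.csv",
  treatments = "treatment.csv",
  careplan = "carePlanGeneral.csv",
  history = "pastHistory.csv")

#' Write raw cohort tables to CSV files
#'
#' One CSV per table, named after the eICU analogs: \code{patient.csv},
#' \code{apachePatientResult.csv}, \code{admissionDx.csv}, \code{lab.csv},
#' \code{vitalPeriodic.csv}, \code{vitalAperiodic.csv}, \code{treatment.csv},
#' \code{carePlanGeneral.csv}, \code{pastHistory.csv}. The stays table is
#' split across the first three files (keyed by \code{stay_id}) and
#' reassembled by \code{\link{read_tables}}.
#'
#' @param tables A \code{raw_tables} object.
#' @param directory Output directory; created if absent.
#' @return Invisibly, the character vector of files written.
#' @export
write_tables <- function(tables, directory) {
  if (!inherits(tables, "raw_tables")) stop("tables must be a raw_tables object")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  st <- tables$stays
  pieces <- list(
    stays_patient = st[c("stay_id", "patient_id", "hospital_id", "beds",
                         "hospital_stay_order", "unit_visit_number",
                         "unit_admit_source", "age", "gender", "bmi", "gcs")],
    stays_apache = st[c("stay_id", "apache_score", "apache_prob", "died")],
    stays_dx = st[c("stay_id", "admission_dx")],
    labs = tables$labs,
    vitals_periodic = tables$vitals_periodic,
    vitals_aperiodic = tables$vitals_aperiodic,
    treatments = tables$treatments,
    careplan = tables$careplan,
    history = tables$history)
  files <- character(0)
  for (nm in names(pieces)) {
    path <- file.path(directory, raw_table_files[[nm]])
    tryCatch(write.csv(pieces[[nm]], path, row.names = FALSE, na = ""),
             error = function(e) stop("failed writing ", path, ": ",
                                      conditionMessage(e)))
    files <- c(files, path)
  }
  invisible(files)
}

#' Read raw cohort tables written by \code{write_tables}
#'
#' @param directory Directory holding the CSV files.
#' @return A \code{raw_tables} object.
#' @export
read_tables <- function(directory) {
  path <- function(nm) {
    f <- file.path(directory, raw_table_files[[nm]])
    if (!file.exists(f)) stop("missing table file: ", f)
    f
  }
  rd <- function(nm, colClasses = NA) {
    read.csv(path(nm), stringsAsFactors = FALSE, colClasses = colClasses,
             na.strings = "")
  }
  pat <- rd("stays_patient")
  apa <- rd("stays_apache")
  dx <- rd("stays_dx")
  stays <- merge(merge(pat, apa, by = "stay_id"), dx, by = "stay_id")
  stays <- stays[order(stays$stay_id),
                 c("stay_id", "patient_id", "hospital_id", "beds",
                   "hospital_stay_order", "unit_visit_number",
                   "unit_admit_source", "age", "gender", "bmi", "gcs",
                   "admission_dx", "apache_score", "apache_prob", "died")]
  rownames(stays) <- NULL
  structure(list(stays = stays,
                 labs = rd("labs"),
                 vitals_periodic = rd("vitals_periodic"),
                 vitals_aperiodic = rd("vitals_aperiodic"),
                 treatments = rd("treatments"),
                 careplan = rd("careplan"),
                 history = rd("history")),
            class = "raw_tables")
}
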