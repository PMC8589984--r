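# Exclusion cascade and holdout split.

require_cols <- function(df, cols, table) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("table '", table, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
}

#' Apply the cohort exclusion cascade
#'
#' Removes, in order: stays with no severity-score mortality prediction;
#' no Glasgow coma scale; admission for lung/heart transplant or burns;
#' age under 16; ICU re-admissions or admissions from another ICU; stays
#' with no periodic vital records. The cohort is then restricted to the
#' last ICU stay of each patient's final hospital stay — patients whose
#' hospital-stay ordering cannot be resolved (a masked/NA ordering on a
#' multi-stay patient) are removed entirely. Finally, stays lacking
#' care-plan records, admission BMI, or medical-history records are
#' removed. Each step is tallied in an exclusion report.
#'
#' @param tables A \code{raw_tables} object (see \code{\link{generate_cohort}}).
#' @return A list with elements \code{tables} (the filtered
#'   \code{raw_tables}) and \code{report} (a data frame with columns
#'   \code{rule}, \code{removed}, \code{remaining}, one row per rule in
#'   application order).
#' @export
#' @examples
#' tabs <- generate_cohort(sim_config(n_stays = 400, n_hospitals = 5, seed = 2))
#' res <- apply_exclusions(tabs)
#' res$report
apply_exclusions <- function(tables) {
  if (!inherits(tables, "raw_tables")) stop("tables must be a raw_tables object")
  st <- tables$stays
  require_cols(st, c("stay_id", "patient_id", "age", "gcs", "apache_prob",
                     "admission_dx", "unit_visit_number", "unit_admit_source",
                     "hospital_stay_order", "bmi"), "stays")
  require_cols(tables$vitals_periodic, "stay_id", "vitals_periodic")

  report <- data.frame(rule = character(0), removed = integer(0),
                       remaining = integer(0))
  drop_rule <- function(st, keep, rule) {
    removed <- sum(!keep)
    st <- st[keep, , drop = FALSE]
    report <<- rbind(report, data.frame(rule = rule, removed = removed,
                                        remaining = nrow(st)))
    st
  }

  st <- drop_rule(st, !is.na(st$apache_prob), "no_apache_score")
  st <- drop_rule(st, !is.na(st$gcs), "no_gcs")
  tb <- grepl("lung transplant|heart transplant|burn", st$admission_dx,
              ignore.case = TRUE)
  st <- drop_rule(st, !tb, "transplant_or_burns")
  st <- drop_rule(st, st$age >= 16, "age_under_16")
  re <- st$unit_visit_number > 1 |
    grepl("other icu", st$unit_admit_source, ignore.case = TRUE)
  st <- drop_rule(st, !re, "readmission_or_other_icu")
  has_vitals <- st$stay_id %in% unique(tables$vitals_periodic$stay_id)
  st <- drop_rule(st, has_vitals, "no_periodic_vitals")

  # last ICU stay in the final hospital stay; unresolvable ordering (NA on
  # a multi-stay patient) removes the patient
  multi <- st$patient_id %in% st$patient_id[duplicated(st$patient_id)]
  unresolvable <- multi & ave(is.na(st$hospital_stay_order), st$patient_id,
                              FUN = any)
  keep_last <- !multi
  if (any(multi & !unresolvable)) {
    idx <- which(multi & !unresolvable)
    sub <- st[idx, ]
    last_order <- ave(sub$hospital_stay_order, sub$patient_id, FUN = max)
    is_final_hs <- sub$hospital_stay_order == last_order
    last_unit <- ave(ifelse(is_final_hs, sub$unit_visit_number, -Inf),
                     sub$patient_id, FUN = max)
    keep_last[idx] <- is_final_hs & sub$unit_visit_number == last_unit
  }
  st <- drop_rule(st, keep_last & !unresolvable, "not_last_stay_or_unresolvable")

  st <- drop_rule(st, st$stay_id %in% tables$careplan$stay_id, "no_careplan")
  st <- drop_rule(st, !is.na(st$bmi), "no_bmi")
  st <- drop_rule(st, st$stay_id %in% tables$history$stay_id, "no_history")

  keep_ids <- st$stay_id
  out <- tables
  out$stays <- st
  for (nm in c("labs", "vitals_periodic", "vitals_aperiodic", "treatments",
               "careplan", "history")) {
    out[[nm]] <- out[[nm]][out[[nm]]$stay_id %in% keep_ids, , drop = FALSE]
    rownames(out[[nm]]) <- NULL
  }
  rownames(out$stays) <- NULL
  stopifnot(nrow(out$stays) == nrow(tables$stays) - sum(report$removed))
  list(tables = out, report = report)
}

#' Randomly split stays into training and holdout sets
#'
#' The holdout size is the fraction of n rounded to the nearest integer
#' (ties to even, the R default). Reproducible under the given seed.
#'
#' @param stay_ids Vector of stay identifiers.
#' @param fraction Holdout fraction, in (0, 1). Default 0.2.
#' @param seed Integer seed.
#' @return A list with elements \code{train} and \code{holdout}, disjoint
#'   id vectors whose union is \code{stay_ids}.
#' @export
#' @examples
#' split_holdout(1:10, fraction = 0.2, seed = 1)
split_holdout <- function(stay_ids, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- length(stay_ids)
  k <- round(fraction * n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hold <- sort(sample(stay_ids, k))
  list(train = setdiff(stay_ids, hold), holdout = hold)
}
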