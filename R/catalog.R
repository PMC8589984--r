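#' Laboratory catalog: worst-value rules, reference ranges, generator targets
#'
#' The per-lab configuration shipped with the package. Each row holds the
#' worst-value direction rule used by feature engineering, the reference
#' range the \code{deviant} and \code{conditional_min} rules need, and the
#' marginal targets (location, spread, severity slope, missingness rate)
#' the synthetic generator draws from. Reference ranges are conventional
#' adult values; they are editable — pass a modified catalog to
#' \code{\link{build_feature_matrix}} or \code{\link{sim_config}} to
#' override.
#'
#' Rule kinds:
#' \describe{
#'   \item{\code{min}}{lowest first-24h value is worst (e.g. albumin, pH).}
#'   \item{\code{max}}{highest value is worst (e.g. lactate, creatinine).}
#'   \item{\code{deviant}}{the value deviating most from the reference range
#'     is worst (glucose, sodium); ties broken towards the higher value.}
#'   \item{\code{conditional_min}}{the minimum is taken only if some value
#'     fell below the lower reference limit, otherwise the maximum (white
#'     blood cells, neutrophils).}
#' }
#'
#' @param file Path to a catalog CSV. Defaults to the copy shipped in
#'   \code{inst/extdata/lab_reference_ranges.csv}.
#' @return A data frame with columns \code{lab}, \code{rule}, \code{low},
#'   \code{high}, \code{mid}, \code{scale}, \code{spread},
#'   \code{severity_slope}, \code{missingness}.
#' @export
#' @examples
#' head(lab_catalog())
lab_catalog <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "lab_reference_ranges.csv",
                        package = "apacheaudit", mustWork = TRUE)
  }
  cat_df <- read.csv(file, stringsAsFactors = FALSE)
  required <- c("lab", "rule", "low", "high", "mid", "scale", "spread",
                "severity_slope", "missingness")
  missing_cols <- setdiff(required, names(cat_df))
  if (length(missing_cols)) {
    stop("lab catalog is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- !cat_df$rule %in% c("min", "max", "deviant", "conditional_min")
  if (any(bad)) {
    stop("unknown rule kind(s): ", paste(unique(cat_df$rule[bad]), collapse = ", "))
  }
  if (any(cat_df$low >= cat_df$high)) stop("reference ranges must have low < high")
  if (any(cat_df$missingness < 0 | cat_df$missingness > 1)) {
    stop("missingness rates must be probabilities")
  }
  cat_df
}

#' Build a worst-value rule for one laboratory test
#'
#' @param lab Lab name.
#' @param rule One of \code{"min"}, \code{"max"}, \code{"deviant"},
#'   \code{"conditional_min"}.
#' @param low,high Reference range; required for \code{deviant} and
#'   \code{conditional_min}.
#' @return An object of class \code{lab_rule}.
#' @export
#' @examples
#' lab_rule("lactate", "max")
#' lab_rule("glucose", "deviant", low = 70, high = 140)
lab_rule <- function(lab, rule = c("min", "max", "deviant", "conditional_min"),
                     low = NA_real_, high = NA_real_) {
  rule <- match.arg(rule)
  if (rule %in% c("deviant", "conditional_min")) {
    if (is.na(low) || is.na(high)) {
      stop("rule '", rule, "' requires a reference range (low, high)")
    }
    if (low >= high) stop("reference range must have low < high")
  }
  structure(list(lab = lab, rule = rule, low = low, high = high),
            class = "lab_rule")
}

#' @export
print.lab_rule <- function(x, ...) {
  rng <- if (is.na(x$low)) "" else sprintf(" [%g, %g]", x$low, x$high)
  cat(sprintf("<lab_rule> %s: %s%s\n", x$lab, x$rule, rng))
  invisible(x)
}

# catalog rows -> named list of lab_rule objects
catalog_rules <- function(catalog = lab_catalog()) {
  rules <- lapply(seq_len(nrow(catalog)), function(i) {
    lab_rule(catalog$lab[i], catalog$rule[i],
             low = catalog$low[i], high = catalog$high[i])
  })
  names(rules) <- catalog$lab
  rules
}

#' Admission-diagnosis category dictionary
#'
#' Keyword dictionary mapping free-text admission diagnoses to 21 categories
#' commonly used for eICU-style cohorts: acute coronary syndrome (the model
#' baseline), acute renal failure, asthma/emphysema, CABG, cardiac arrest,
#' chest pain, congestive heart failure, coma, stroke (CVA), diabetic
#' ketoacidosis, GI bleed, GI obstruction, neurologic problems, overdose,
#' pneumonia, sepsis, trauma, valve repair/replacement, other cerebrovascular
#' problems, other respiratory problems, and other diagnoses. Matching is
#' case-insensitive, first match in the listed order wins, and unmatched
#' text falls through to \code{other}.
#'
#' @return Named list of regular-expression keyword vectors; names are the
#'   category codes in match order, with \code{other} last.
#' @export
#' @examples
#' names(admission_dx_dictionary())
admission_dx_dictionary <- function() {
  list(
    cabg            = c("coronary artery bypass", "cabg"),
    valve_disease   = c("valve repair", "valve replacement", "valvular"),
    cardiac_arrest  = c("cardiac arrest", "cardiopulmonary arrest"),
    chest_pain      = c("chest pain"),  # before ACS: "chest pain, r/o MI"
    acs             = c("acute coronary syndrome", "myocardial infarction",
                        "\\bacs\\b", "\\bmi\\b", "unstable angina"),
    chf             = c("congestive heart failure", "\\bchf\\b",
                        "pulmonary edema"),
    cva             = c("\\bcva\\b", "stroke", "cerebrovascular accident"),
    other_cerebrovascular = c("subarachnoid", "intracranial hemorrhage",
                              "aneurysm, cerebral", "cerebrovascular"),
    coma            = c("\\bcoma\\b", "unresponsive"),
    neurologic      = c("seizure", "neurologic", "encephalopathy",
                        "neuromuscular"),
    dka             = c("diabetic ketoacidosis", "\\bdka\\b"),
    arf             = c("acute renal failure", "renal failure, acute"),
    gi_bleed        = c("gi bleed", "gastrointestinal bleed",
                        "bleeding, upper gi", "bleeding, lower gi"),
    gi_obstruction  = c("gi obstruction", "bowel obstruction"),
    overdose        = c("overdose", "drug ingestion", "toxicity, drug"),
    pneumonia       = c("pneumonia", "\\bpna\\b"),
    asthma_emphysema = c("asthma", "emphysema", "\\bcopd\\b",
                         "chronic obstructive"),
    other_respiratory = c("respiratory failure", "respiratory distress",
                          "pulmonary embolism", "respiratory"),
    sepsis          = c("sepsis", "septic shock"),
    trauma          = c("trauma", "motor vehicle", "\\bfall\\b",
                        "gunshot", "injury"),
    other           = character(0)
  )
}

# categories in canonical order; `acs` is the indicator baseline
dx_categories <- function() names(admission_dx_dictionary())
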