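#' Configuration for the synthetic eICU-shaped cohort generator
#'
#' Collects every knob of \code{\link{generate_cohort}} with validated
#' defaults. The defaults encode the study conditions the audit emulates:
#' an observed in-hospital mortality near 9.9\%, a severity score whose mean
#' predicted mortality overshoots observed mortality by a factor of about
#' 1.21 (11.96\% vs 9.91\%), per-lab missingness spanning 3\% (creatinine)
#' to 95\% (amylase), and two planted first-24h predictors of score errors:
#' a protective treatment flag the score does not see (vasopressor, log-odds
#' -0.8 on death, a Type I error predictor among predicted deaths) and a
#' risk-raising history flag (COPD, log-odds +0.8, a Type II error predictor
#' among predicted survivors).
#'
#' @param n_stays Number of ICU stays to generate (before exclusions).
#' @param n_hospitals Number of hospitals.
#' @param hospital_size_weights Probabilities over the four bed-size classes
#'   \code{very_small} (< 100 beds), \code{small} (100-249), \code{medium}
#'   (250-499), \code{large} (>= 500); must sum to 1.
#' @param target_observed_mortality Cohort in-hospital death rate.
#' @param overprediction_factor Ratio of mean predicted to mean observed
#'   mortality; must be >= 1. 1 yields a calibrated score.
#' @param prediction_noise_sd SD of the noise added to the score's linear
#'   predictor, controlling how sharply the score tracks true risk.
#' @param lab_missingness Named vector of per-lab probabilities that a stay
#'   has no measurement of that lab in the first 24 h; defaults to the
#'   catalog column. Values must lie in [0, 1].
#' @param planted_effects Named list: feature name ->
#'   \code{list(type = "type1"|"type2", beta = log-odds)}. The effect enters
#'   the death model (negated for \code{type1}, so the feature promotes
#'   survival) but is hidden from the severity score, creating the planted
#'   error association. Allowed names: \code{vasopressor},
#'   \code{ventilated_day1}, \code{care_limitation}, and the \code{hx_*}
#'   history flags.
#' @param hospital_effect_sd SD of an optional hospital-level random
#'   intercept on the death model; 0 (default) means none.
#' @param exclusion_fractions Named list of small fractions of stays planted
#'   to trigger each exclusion rule (see \code{\link{apply_exclusions}}).
#' @param catalog Lab catalog data frame, see \code{\link{lab_catalog}}.
#' @param seed Master integer seed; all child streams derive from it.
#' @return An object of class \code{sim_config}.
#' @export
#' @examples
#' cfg <- sim_config(n_stays = 500, seed = 1)
#' cfg$overprediction_factor
sim_config <- function(n_stays = 20000,
                       n_hospitals = 40,
                       hospital_size_weights = c(very_small = 0.25,
                                                 small = 0.35,
                                                 medium = 0.25,
                                                 large = 0.15),
                       target_observed_mortality = 0.099,
                       overprediction_factor = 1.207,
                       prediction_noise_sd = 0.5,
                       lab_missingness = NULL,
                       planted_effects = list(
                         vasopressor = list(type = "type1", beta = 0.8),
                         hx_copd     = list(type = "type2", beta = 0.8)),
                       hospital_effect_sd = 0,
                       exclusion_fractions = list(
                         missing_apache = 0.010,
                         missing_gcs    = 0.008,
                         transplant_burn = 0.004,
                         under_16       = 0.004,
                         readmission    = 0.010,
                         no_vitals      = 0.004,
                         multi_hospital_stay = 0.010,
                         unresolvable_order  = 0.004,
                         missing_bmi     = 0.004,
                         missing_history = 0.003,
                         missing_careplan = 0.003),
                       catalog = lab_catalog(),
                       seed = 1L) {
  if (length(n_stays) != 1 || is.na(n_stays) || n_stays <= 0) {
    stop("n_stays must be a positive count")
  }
  n_stays <- as.integer(n_stays)
  n_hospitals <- as.integer(n_hospitals)
  if (n_hospitals <= 0) stop("n_hospitals must be a positive count")
  if (n_stays < n_hospitals) stop("n_stays must be >= n_hospitals")

  stopifnot(length(hospital_size_weights) == 4)
  if (any(hospital_size_weights < 0) ||
      abs(sum(hospital_size_weights) - 1) > 1e-8) {
    stop("hospital_size_weights must be non-negative and sum to 1")
  }
  if (target_observed_mortality <= 0 || target_observed_mortality >= 1) {
    stop("target_observed_mortality must be in (0, 1)")
  }
  if (overprediction_factor < 1) stop("overprediction_factor must be >= 1")
  if (overprediction_factor * target_observed_mortality >= 1) {
    stop("overprediction_factor * target_observed_mortality must be < 1")
  }

  if (is.null(lab_missingness)) {
    lab_missingness <- setNames(catalog$missingness, catalog$lab)
  }
  unknown <- setdiff(names(lab_missingness), catalog$lab)
  if (length(unknown)) {
    stop("lab_missingness names not in catalog: ",
         paste(unknown, collapse = ", "))
  }
  if (any(lab_missingness < 0 | lab_missingness > 1)) {
    stop("lab_missingness rates must be in [0, 1]")
  }
  miss <- setNames(catalog$missingness, catalog$lab)
  miss[names(lab_missingness)] <- lab_missingness

  plantable <- c("vasopressor", "ventilated_day1", "care_limitation",
                 "hx_copd", "hx_diabetes", "hx_chf", "hx_renal", "hx_cancer")
  if (length(planted_effects)) {
    bad <- setdiff(names(planted_effects), plantable)
    if (length(bad)) {
      stop("planted effect on unknown feature name(s): ",
           paste(bad, collapse = ", "),
           " (allowed: ", paste(plantable, collapse = ", "), ")")
    }
    for (pe in planted_effects) {
      if (!is.list(pe) || !pe$type %in% c("type1", "type2") ||
          !is.numeric(pe$beta)) {
        stop("each planted effect must be list(type = 'type1'|'type2', beta = <numeric>)")
      }
    }
  }

  structure(list(
    n_stays = n_stays,
    n_hospitals = n_hospitals,
    hospital_size_weights = hospital_size_weights,
    target_observed_mortality = target_observed_mortality,
    overprediction_factor = overprediction_factor,
    prediction_noise_sd = prediction_noise_sd,
    lab_missingness = miss,
    planted_effects = planted_effects,
    hospital_effect_sd = hospital_effect_sd,
    exclusion_fractions = exclusion_fractions,
    catalog = catalog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  stays: %d across %d hospitals\n", x$n_stays, x$n_hospitals))
  cat(sprintf("  observed mortality target: %.3f; overprediction factor: %.3f\n",
              x$target_observed_mortality, x$overprediction_factor))
  cat(sprintf("  labs: %d, missingness %.2f-%.2f\n",
              length(x$lab_missingness), min(x$lab_missingness),
              max(x$lab_missingness)))
  if (length(x$planted_effects)) {
    for (nm in names(x$planted_effects)) {
      pe <- x$planted_effects[[nm]]
      cat(sprintf("  planted: %s -> %s (beta %.2f)\n", nm, pe$type, pe$beta))
    }
  }
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# deterministic child seeds, one per named stream; documented order
child_seeds <- function(seed, streams = c("hospitals", "stays", "history",
                                          "careplan", "treatments", "dx",
                                          "outcome", "labs",
                                          "vitals_periodic",
                                          "vitals_aperiodic",
                                          "exclusions")) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(streams)), streams)
}
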