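# APACHE Relative Confidence (ARC), cutoff calibration, error labelling.

check_cutoff <- function(cutoff) {
  if (length(cutoff) != 1 || is.na(cutoff) || cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must be a single probability in (0, 1)")
  }
  cutoff
}

#' APACHE Relative Confidence (ARC)
#'
#' Normalized distance from the score's predicted mortality probability to
#' the classification cutoff: \code{(cutoff - p) / cutoff} when
#' \code{p <= cutoff}, \code{(p - cutoff) / (1 - cutoff)} when
#' \code{p > cutoff}. ARC is 0 exactly at the cutoff, 1 at both endpoints
#' of [0, 1], and piecewise linear in between; larger values indicate a
#' more confident (more extreme) prediction.
#'
#' @param apache_prob Numeric vector of predicted mortality probabilities,
#'   each in [0, 1].
#' @param cutoff Classification cutoff, a probability in (0, 1).
#' @return Numeric vector of ARC values in [0, 1].
#' @export
#' @examples
#' compute_arc(c(0, 0.165, 0.33, 1), cutoff = 0.33)
compute_arc <- function(apache_prob, cutoff) {
  check_cutoff(cutoff)
  if (any(apache_prob < 0 | apache_prob > 1, na.rm = TRUE)) {
    stop("apache_prob values must lie in [0, 1]")
  }
  ifelse(apache_prob <= cutoff,
         (cutoff - apache_prob) / cutoff,
         (apache_prob - cutoff) / (1 - cutoff))
}

#' Calibrate the classification cutoff to the observed mortality rate
#'
#' Returns the cutoff c at which the fraction of predictions strictly
#' greater than c best matches the observed mortality rate, i.e. the score
#' classifies the same share of stays as deaths as actually die. The search
#' grid is all distinct predicted probabilities inside (0, 1) together with
#' a 0.001-step lattice; ties in the objective go to the smallest cutoff.
#'
#' @param apache_probs Non-empty numeric vector of predicted probabilities.
#' @param observed_mortality_rate Observed death rate, in (0, 1).
#' @return A list of class \code{cutoff_spec} with elements \code{value},
#'   \code{origin} (\code{"calibrated"}), \code{classified_rate} (the
#'   achieved fraction above the cutoff) and \code{target_rate}.
#' @export
#' @examples
#' calibrate_cutoff(runif(1000), observed_mortality_rate = 0.1)$value
calibrate_cutoff <- function(apache_probs, observed_mortality_rate) {
  if (!length(apache_probs)) stop("apache_probs must be non-empty")
  if (observed_mortality_rate <= 0 || observed_mortality_rate >= 1) {
    stop("observed_mortality_rate must be in the open interval (0, 1)")
  }
  grid <- sort(unique(c(seq(0.001, 0.999, by = 0.001),
                        apache_probs[apache_probs > 0 & apache_probs < 1])))
  n <- length(apache_probs)
  # fraction strictly above each grid point, via one sort
  frac_above <- 1 - findInterval(grid, sort(apache_probs)) / n
  obj <- abs(frac_above - observed_mortality_rate)
  best <- which(obj == min(obj))[1]  # grid sorted ascending: first = smallest c
  structure(list(value = grid[best], origin = "calibrated",
                 classified_rate = frac_above[best],
                 target_rate = observed_mortality_rate),
            class = "cutoff_spec")
}

#' @export
print.cutoff_spec <- function(x, ...) {
  cat(sprintf("<cutoff_spec> %.4f (%s): %.2f%% classified as deaths vs %.2f%% observed\n",
              x$value, x$origin, 100 * x$classified_rate, 100 * x$target_rate))
  invisible(x)
}

#' Label severity-score prediction errors
#'
#' A stay is predicted to die when its probability strictly exceeds the
#' cutoff (equality maps to predicted survival, consistent with ARC's
#' left branch). A Type I error is a predicted death who survived (false
#' positive); a Type II error is a predicted survivor who died (false
#' negative).
#'
#' @param apache_prob Predicted mortality probabilities in [0, 1].
#' @param cutoff Classification cutoff in (0, 1) (a number or a
#'   \code{cutoff_spec}).
#' @param died Binary in-hospital death indicator.
#' @param stay_id Optional identifiers carried through.
#' @return A data frame of class \code{error_labels} with columns
#'   \code{stay_id} (if given), \code{apache_prob}, \code{predicted_death},
#'   \code{died}, \code{type1}, \code{type2}, \code{arc}.
#' @export
#' @examples
#' label_errors(c(0.6, 0.1, 0.6), 0.33, died = c(0, 1, 1))
label_errors <- function(apache_prob, cutoff, died, stay_id = NULL) {
  if (inherits(cutoff, "cutoff_spec")) cutoff <- cutoff$value
  check_cutoff(cutoff)
  died <- as.integer(died)
  if (length(died) != length(apache_prob)) {
    stop("apache_prob and died must have equal length")
  }
  predicted_death <- as.integer(apache_prob > cutoff)
  out <- data.frame(
    apache_prob = apache_prob,
    predicted_death = predicted_death,
    died = died,
    type1 = as.integer(predicted_death == 1L & died == 0L),
    type2 = as.integer(predicted_death == 0L & died == 1L),
    arc = compute_arc(apache_prob, cutoff))
  if (!is.null(stay_id)) out <- cbind(stay_id = stay_id, out)
  class(out) <- c("error_labels", "data.frame")
  attr(out, "cutoff") <- cutoff
  out
}

#' Error rates by ARC bin
#'
#' Splits [0, 1] into equal-width ARC bins and reports, per bin, the Type I
#' error rate among stays predicted to die and the Type II error rate among
#' stays predicted to survive. Empty bins (no stays on the relevant
#' prediction side) are reported as \code{NA}.
#'
#' @param labels An \code{error_labels} data frame.
#' @param n_bins Number of bins, at least 2. Default 10.
#' @return Data frame with columns \code{arc_mid}, \code{n_predicted_death},
#'   \code{type1_rate}, \code{n_predicted_survive}, \code{type2_rate}.
#' @export
error_rate_by_arc_bin <- function(labels, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be at least 2")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(labels$arc, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  t1_n <- t1_rate <- t2_n <- t2_rate <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    pd <- labels$predicted_death == 1 & bin == b
    ps <- labels$predicted_death == 0 & bin == b
    t1_n[b] <- sum(pd)
    t2_n[b] <- sum(ps)
    if (t1_n[b] > 0) t1_rate[b] <- mean(labels$type1[pd])
    if (t2_n[b] > 0) t2_rate[b] <- mean(labels$type2[ps])
  }
  data.frame(arc_mid = mids,
             n_predicted_death = as.integer(t1_n), type1_rate = t1_rate,
             n_predicted_survive = as.integer(t2_n), type2_rate = t2_rate)
}
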