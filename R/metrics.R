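# Imbalance-aware evaluation: confusion metrics, F-score, AUROC/AUPRC,
# hospital-level calibration, lab-missingness accounting.

#' Confusion-matrix metrics
#'
#' Counts TP/TN/FP/FN and derives precision, recall, F-score and accuracy.
#' Precision (or recall) with a zero denominator is reported as \code{NA}
#' with a warning, as is the F-score when either input is undefined.
#'
#' @param truth Binary 0/1 vector of true labels.
#' @param predicted Binary 0/1 vector of predicted labels, same length.
#' @return A list of class \code{metrics_report}: \code{tp}, \code{tn},
#'   \code{fp}, \code{fn}, \code{precision}, \code{recall},
#'   \code{f_score}, \code{accuracy} (plus \code{auroc}/\code{auprc}/
#'   \code{pop_error_rate} slots filled by callers).
#' @export
#' @examples
#' confusion_metrics(c(1,1,0,0,1,0,0,0,1,0), c(1,1,1,0,0,0,0,0,0,0))
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  tp <- sum(truth == 1 & predicted == 1)
  tn <- sum(truth == 0 & predicted == 0)
  fp <- sum(truth == 0 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no positive predictions; precision undefined"); NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive labels; recall undefined"); NA_real_
  }
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    f_score(precision, recall)
  } else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 precision = precision, recall = recall, f_score = f,
                 accuracy = (tp + tn) / length(truth),
                 auroc = NA_real_, auprc = NA_real_,
                 pop_error_rate = NA_real_),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> TP %d TN %d FP %d FN %d\n", x$tp, x$tn,
              x$fp, x$fn))
  cat(sprintf("  precision %.4f recall %.4f F %.4f accuracy %.4f\n",
              x$precision, x$recall, x$f_score, x$accuracy))
  if (!is.na(x$auroc)) {
    cat(sprintf("  AUROC %.4f AUPRC %.4f\n", x$auroc, x$auprc))
  }
  invisible(x)
}

#' F-score (harmonic mean of precision and recall)
#'
#' \code{2 * precision * recall / (precision + recall)}.
#'
#' @param precision,recall Values in [0, 1], not both zero.
#' @return The F-score.
#' @export
#' @examples
#' f_score(0.6248, 0.7754)
f_score <- function(precision, recall) {
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1)) {
    stop("precision and recall must lie in [0, 1]")
  }
  if (any(precision + recall == 0)) stop("precision + recall must be positive")
  2 * precision * recall / (precision + recall)
}

#' Ranking metrics: AUROC and AUPRC
#'
#' AUROC is computed by the tie-corrected Mann-Whitney rank statistic.
#' AUPRC uses step interpolation of the precision-recall curve over the
#' distinct score thresholds (average-precision convention: each increment
#' of recall is weighted by the precision at that threshold).
#'
#' @param scores Real-valued scores, higher meaning more positive.
#' @param truth Binary 0/1 labels; both classes must be present.
#' @return List with \code{auroc} and \code{auprc}.
#' @export
#' @examples
#' ranking_metrics(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
ranking_metrics <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  auroc <- (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # threshold sweep over distinct scores, descending
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  grp_end <- cumsum(rle(s)$lengths)  # last index of each tie group
  tp <- cumsum(y)[grp_end]
  pos_pred <- grp_end
  prec <- tp / pos_pred
  rec <- tp / n1
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, auprc = auprc)
}

#' Hospital-level calibration of predicted vs observed mortality
#'
#' Per hospital: observed in-hospital mortality, mean predicted mortality,
#' bed-size class (very small < 100 beds; small 100-249; medium 250-499;
#' large >= 500), and whether the hospital falls below the identity
#' diagonal (observed < predicted, i.e. the score overpredicts there).
#'
#' @param stays Data frame with columns \code{hospital_id}, \code{beds},
#'   \code{apache_prob}, \code{died}.
#' @return Data frame with one row per hospital: \code{hospital_id},
#'   \code{n_stays}, \code{beds}, \code{size_class},
#'   \code{observed_mortality}, \code{predicted_mortality},
#'   \code{below_diagonal}.
#' @export
hospital_calibration <- function(stays) {
  required <- c("hospital_id", "beds", "apache_prob", "died")
  miss <- setdiff(required, names(stays))
  if (length(miss)) stop("stays is missing column(s): ",
                         paste(miss, collapse = ", "))
  hid <- stays$hospital_id
  obs <- tapply(stays$died, hid, mean)
  pred <- tapply(stays$apache_prob, hid, mean)
  nb <- tapply(stays$beds, hid, function(b) b[1])
  n <- tapply(stays$died, hid, length)
  size_class <- cut(nb, breaks = c(-Inf, 99.5, 249.5, 499.5, Inf),
                    labels = c("very_small", "small", "medium", "large"))
  out <- data.frame(hospital_id = names(obs),
                    n_stays = as.integer(n),
                    beds = as.numeric(nb),
                    size_class = as.character(size_class),
                    observed_mortality = as.numeric(obs),
                    predicted_mortality = as.numeric(pred))
  out$below_diagonal <- out$observed_mortality < out$predicted_mortality
  rownames(out) <- NULL
  out
}

#' Patient-by-lab measurement accounting
#'
#' Counts, over every (stay, lab) combination of the cohort, how many
#' combinations have no first-24h measurement (the missing cells the
#' imputation strategies must fill), exactly one measurement (that value
#' is the worst value by convention), and two or more (the direction rule
#' applies), together with percentages of all combinations. Percentages
#' are reported to one decimal.
#'
#' @param tables A \code{raw_tables} object; or pass \code{counts}, a
#'   named vector \code{c(none =, one =, two_plus =)}, to redo the
#'   arithmetic on externally tallied counts.
#' @param counts Optional pre-tallied counts (overrides \code{tables}).
#' @param catalog Lab catalog naming the labs audited.
#' @return Data frame with columns \code{category}, \code{count},
#'   \code{percent}; attribute \code{total} holds the number of
#'   combinations.
#' @export
#' @examples
#' lab_measurement_accounting(counts = c(none = 2, one = 1, two_plus = 3))
lab_measurement_accounting <- function(tables = NULL, counts = NULL,
                                       catalog = lab_catalog()) {
  if (is.null(counts)) {
    if (!inherits(tables, "raw_tables")) {
      stop("provide a raw_tables object or explicit counts")
    }
    n_stays <- nrow(tables$stays)
    n_labs <- nrow(catalog)
    tab <- table(factor(tables$labs$lab, levels = catalog$lab),
                 factor(tables$labs$stay_id, levels = tables$stays$stay_id))
    n_one <- sum(tab == 1)
    n_two <- sum(tab >= 2)
    counts <- c(none = n_stays * n_labs - n_one - n_two,
                one = n_one, two_plus = n_two)
  }
  counts <- counts[c("none", "one", "two_plus")]
  if (anyNA(counts)) stop("counts must name none, one, two_plus")
  total <- sum(counts)
  out <- data.frame(category = names(counts),
                    count = as.numeric(counts),
                    percent = round(100 * as.numeric(counts) / total, 1))
  attr(out, "total") <- total
  out
}
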