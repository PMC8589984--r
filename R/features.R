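# First-24h feature engineering: worst lab values, vital summaries,
# diagnosis indicators, standardization.

#' Worst value of a laboratory test under its direction rule
#'
#' An empty measurement list yields \code{NA}; a single measurement is its
#' own worst value; otherwise the rule decides: \code{min}/\code{max} take
#' the extreme; \code{deviant} takes the value deviating most from the
#' reference range, measured as \code{max(low - x, x - high)} (negative
#' inside the range), ties broken towards the higher value;
#' \code{conditional_min} takes the minimum only if any measurement fell
#' below the lower reference limit, else the maximum.
#'
#' @param values Numeric vector of first-24h measurements (NAs dropped).
#' @param rule A \code{\link{lab_rule}}.
#' @return A single numeric value, or \code{NA} if no measurements.
#' @export
#' @examples
#' worst_lab_value(c(1.2, 3.1, 5.0), lab_rule("lactate", "max"))
#' worst_lab_value(c(65, 150), lab_rule("glucose", "deviant", 70, 140))
worst_lab_value <- function(values, rule) {
  if (!inherits(rule, "lab_rule")) stop("rule must be a lab_rule")
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  if (length(values) == 1) return(values)
  switch(rule$rule,
    min = min(values),
    max = max(values),
    deviant = {
      lo <- min(values); hi <- max(values)
      dev <- function(x) max(rule$low - x, x - rule$high)
      if (dev(hi) >= dev(lo)) hi else lo
    },
    conditional_min = if (any(values < rule$low)) min(values) else max(values),
    stop("unknown rule kind: ", rule$rule))
}

# grouped min/max/mean over a long table, vectorized; returns named vector
grouped_stat <- function(value, group, levels, fun) {
  out <- rep(NA_real_, length(levels))
  names(out) <- as.character(levels)
  if (!length(value)) return(out)
  g <- factor(group, levels = levels)
  res <- tapply(value, g, fun)
  out[names(res)] <- as.numeric(res)
  out
}

#' Summarize first-24h vital-sign series
#'
#' Computes the arithmetic mean plus the minimum and maximum of each vital.
#' The direction of a vital's "worst" value is context dependent (low SpO2
#' is bad, but heart rate can be bad high or low), so both extremes are
#' emitted and downstream feature selection decides which carries signal.
#'
#' @param series Numeric vector of measurements for one stay.
#' @return Named numeric vector \code{c(mean, min, max)}; all \code{NA}
#'   for an empty series.
#' @export
#' @examples
#' summarize_vitals(c(98, 92, 95))
summarize_vitals <- function(series) {
  series <- series[!is.na(series)]
  if (!length(series)) return(c(mean = NA_real_, min = NA_real_, max = NA_real_))
  c(mean = mean(series), min = min(series), max = max(series))
}

#' Map admission-diagnosis text to a category and indicator block
#'
#' Matches the text against the keyword dictionary
#' (\code{\link{admission_dx_dictionary}}); unmatched text falls into
#' \code{other}. Acute coronary syndrome (\code{acs}) is the baseline: its
#' indicators are all zero, so the block has 20 columns for 21 categories.
#'
#' @param text Character vector of admission diagnoses.
#' @return A list with \code{category} (character vector) and
#'   \code{indicators} (matrix of 0/1 with one \code{dx_*} column per
#'   non-baseline category; row sums are 0 for \code{acs} and 1 otherwise).
#' @export
#' @examples
#' encode_admission_dx("Sepsis, pulmonary")$category
encode_admission_dx <- function(text) {
  dict <- admission_dx_dictionary()
  category <- rep("other", length(text))
  unmatched <- rep(TRUE, length(text))
  for (cat_name in setdiff(names(dict), "other")) {
    pat <- paste(dict[[cat_name]], collapse = "|")
    hit <- unmatched & grepl(pat, text, ignore.case = TRUE)
    category[hit] <- cat_name
    unmatched <- unmatched & !hit
  }
  non_base <- setdiff(names(dict), "acs")
  ind <- sapply(non_base, function(cc) as.integer(category == cc))
  ind <- matrix(ind, nrow = length(text),
                dimnames = list(NULL, paste0("dx_", non_base)))
  list(category = category, indicators = ind)
}

#' Build the per-stay feature matrix from first-24h data
#'
#' Assembles, per stay: mean/min/max of each periodic vital (heart rate,
#' respiratory rate, SpO2), the mean aperiodic vital (mean of first-24h
#' aperiodic blood-pressure values), the worst value of each catalog lab,
#' treatment flags (vasopressor, ventilated day 1), the care-limitation
#' change count, medical-history flags, age, BMI, and
#' 20 admission-diagnosis indicators. Lab columns may contain \code{NA}
#' (test not performed); all other columns are complete on a cohort that
#' passed \code{\link{apply_exclusions}}.
#'
#' @param tables A filtered \code{raw_tables} object.
#' @param catalog Lab catalog; defaults to \code{\link{lab_catalog}()}.
#' @return An object of class \code{feature_matrix}: a list with \code{x}
#'   (data frame, first column \code{stay_id}), \code{lab_cols} (names of
#'   worst-lab columns), and \code{provenance} (named character vector
#'   recording each column's source).
#' @export
build_feature_matrix <- function(tables, catalog = lab_catalog()) {
  if (!inherits(tables, "raw_tables")) stop("tables must be a raw_tables object")
  st <- tables$stays
  ids <- st$stay_id
  x <- data.frame(stay_id = ids)
  prov <- c()

  ## vitals
  vp <- tables$vitals_periodic
  if (any(vp$offset_hours < 0 | vp$offset_hours > 24)) {
    stop("periodic vital offsets must lie in [0, 24] hours")
  }
  for (v in c("heart_rate", "respiratory_rate", "spo2")) {
    short <- c(heart_rate = "hr", respiratory_rate = "rr", spo2 = "spo2")[[v]]
    for (stat in c("mean", "min", "max")) {
      fun <- switch(stat, mean = mean, min = min, max = max)
      col <- paste0(stat, "_", short)
      x[[col]] <- unname(grouped_stat(vp[[v]], vp$stay_id, ids, fun))
      prov[col] <- "vital_periodic"
    }
  }
  va <- tables$vitals_aperiodic
  x$mean_aperiodic_vital <- unname(grouped_stat(va$mean_bp, va$stay_id, ids, mean))
  prov["mean_aperiodic_vital"] <- "vital_aperiodic"

  ## worst labs: min/max vectorized via tapply; deviant/conditional need
  ## both extremes plus the below-lower indicator
  labs <- tables$labs
  for (i in seq_len(nrow(catalog))) {
    lab <- catalog$lab[i]
    sub <- labs[labs$lab == lab, ]
    col <- paste0("worst_", lab)
    lo <- grouped_stat(sub$value, sub$stay_id, ids, min)
    hi <- grouped_stat(sub$value, sub$stay_id, ids, max)
    x[[col]] <- unname(switch(catalog$rule[i],
      min = lo,
      max = hi,
      deviant = {
        dev_lo <- catalog$low[i] - lo
        dev_hi <- hi - catalog$high[i]
        ifelse(dev_hi >= dev_lo, hi, lo)
      },
      conditional_min = ifelse(lo < catalog$low[i], lo, hi)))
    prov[col] <- "lab"
  }

  ## treatments, care plan, history
  # lactate_test stays in the treatments table but out of the feature
  # matrix: it is the exact complement of the miss_lactate flag the
  # median-flag imputation emits, and duplicating it aliases the refit
  tr <- tables$treatments[match(ids, tables$treatments$stay_id), ]
  x$vasopressor <- tr$vasopressor
  x$ventilated_day1 <- tr$ventilated_day1
  prov[c("vasopressor", "ventilated_day1")] <- "treatment"
  cp <- tables$careplan[match(ids, tables$careplan$stay_id), ]
  x$care_limitation <- cp$care_limitation
  prov["care_limitation"] <- "careplan"
  hx <- tables$history[match(ids, tables$history$stay_id), ]
  for (col in setdiff(names(hx), "stay_id")) {
    x[[col]] <- hx[[col]]
    prov[col] <- "history"
  }

  ## demographics and diagnoses
  x$age <- st$age
  x$bmi <- st$bmi
  prov[c("age", "bmi")] <- "demographic"
  enc <- encode_admission_dx(st$admission_dx)
  for (col in colnames(enc$indicators)) {
    x[[col]] <- enc$indicators[, col]
    prov[col] <- "admission_dx"
  }

  structure(list(x = x,
                 lab_cols = paste0("worst_", catalog$lab),
                 provenance = prov),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d stays x %d features (%d lab columns, %d NA cells)\n",
              nrow(x$x), ncol(x$x) - 1, length(x$lab_cols),
              sum(is.na(x$x[x$lab_cols]))))
  invisible(x)
}

#' Standardize feature columns to mean 0 and variance 1
#'
#' Centering and scaling parameters are estimated on the fitting rows only
#' (sample SD, divisor n-1) and applied to every row, so a holdout set is
#' transformed with training-set parameters. Zero-variance columns on the
#' fitting rows are dropped with a warning.
#'
#' @param x Data frame or matrix of numeric feature columns (no id column).
#' @param fit_rows Integer or logical index of rows used to estimate
#'   parameters; defaults to all rows.
#' @return A list with \code{x} (standardized matrix), \code{center} and
#'   \code{scale} (named parameter vectors), and \code{dropped} (names of
#'   removed zero-variance columns).
#' @export
#' @examples
#' standardize_features(data.frame(a = c(0, 2), b = c(5, 9)))$x
standardize_features <- function(x, fit_rows = seq_len(nrow(x))) {
  xm <- as.matrix(x)
  if (!is.numeric(xm)) stop("all feature columns must be numeric")
  fit <- xm[fit_rows, , drop = FALSE]
  if (nrow(fit) == 0) stop("fit_rows must be non-empty")
  ctr <- colMeans(fit, na.rm = TRUE)
  scl <- apply(fit, 2, sd, na.rm = TRUE)
  dropped <- colnames(xm)[is.na(scl) | scl < 1e-12]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    keep <- setdiff(colnames(xm), dropped)
    xm <- xm[, keep, drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]
  }
  xs <- sweep(sweep(xm, 2, ctr, "-"), 2, scl, "/")
  list(x = xs, center = ctr, scale = scl, dropped = dropped)
}
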