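# Three laboratory missing-data strategies. All operate on the lab columns
# of a feature_matrix, leave observed cells untouched, and record a per-lab
# ledger of imputed-cell counts.

impute_input <- function(features) {
  if (!inherits(features, "feature_matrix")) {
    stop("features must be a feature_matrix")
  }
  lab_cols <- intersect(features$lab_cols, names(features$x))
  if (!length(lab_cols)) stop("feature matrix has no lab columns")
  lab_cols
}

finish_imputation <- function(features, filled, method, flags = NULL) {
  lab_cols <- intersect(features$lab_cols, names(features$x))
  ledger <- vapply(lab_cols, function(cc) sum(is.na(features$x[[cc]])),
                   integer(1))
  out <- features
  out$x[lab_cols] <- filled[lab_cols]
  if (!is.null(flags)) {
    for (cc in names(flags)) {
      out$x[[cc]] <- flags[[cc]]
      out$provenance[cc] <- "missingness_flag"
    }
  }
  structure(list(features = out, method = method, flags = flags,
                 ledger = ledger),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> method %s: %d cells imputed across %d labs\n",
              x$method, sum(x$ledger), sum(x$ledger > 0)))
  invisible(x)
}

check_all_missing <- function(x, cols, fit_rows) {
  all_na <- cols[vapply(cols, function(cc) all(is.na(x[fit_rows, cc])),
                        logical(1))]
  if (length(all_na)) {
    stop("column(s) entirely missing on the fitting rows: ",
         paste(all_na, collapse = ", "))
  }
}

#' Multiple imputation of missing lab values (averaged completions)
#'
#' Chained-equation imputation: starting from mean fills, each incomplete
#' lab column is repeatedly regressed on all other lab and vital columns
#' (ordinary least squares on the observed rows of the fitting split) and
#' its missing cells are redrawn as prediction plus Gaussian residual
#' noise, for a fixed 10 sweeps. This is repeated for \code{m} independent
#' completions and each missing cell is replaced by the mean of its
#' \code{m} imputed values, yielding one pooled completed dataset for the
#' downstream model.
#'
#' @param features A \code{feature_matrix}.
#' @param m Number of imputations, at least 2. Default 10.
#' @param seed Integer seed; the result is deterministic given it.
#' @param fit_rows Rows used to estimate the imputation regressions
#'   (training split); defaults to all rows.
#' @return An \code{imputation_result}.
#' @export
impute_multiple <- function(features, m = 10, seed = 1L,
                            fit_rows = seq_len(nrow(features$x))) {
  if (m < 2) stop("m must be at least 2")
  lab_cols <- impute_input(features)
  x <- features$x
  check_all_missing(x, lab_cols, fit_rows)
  vital_cols <- names(features$provenance)[
    features$provenance %in% c("vital_periodic", "vital_aperiodic")]
  pred_cols <- intersect(c(lab_cols, vital_cols), names(x))
  xm <- as.matrix(x[pred_cols])
  miss <- is.na(xm)
  target_cols <- lab_cols[colSums(miss[, lab_cols, drop = FALSE]) > 0]
  if (!length(target_cols)) {
    return(finish_imputation(features, x, "multiple-imputation"))
  }
  fit_mask <- rep(FALSE, nrow(xm)); fit_mask[fit_rows] <- TRUE

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  acc <- matrix(0, nrow(xm), length(target_cols),
                dimnames = list(NULL, target_cols))
  for (imp in seq_len(m)) {
    cur <- xm
    mu <- colMeans(cur[fit_mask, , drop = FALSE], na.rm = TRUE)
    for (j in seq_len(ncol(cur))) cur[miss[, j], j] <- mu[j]
    for (iter in 1:10) {
      for (tc in target_cols) {
        obs <- fit_mask & !miss[, tc]
        X <- cbind(1, cur[, setdiff(pred_cols, tc), drop = FALSE])
        fit <- lm.fit(X[obs, , drop = FALSE], cur[obs, tc])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0  # rank-deficient predictors contribute nothing
        sigma <- sqrt(sum(fit$residuals^2) / max(sum(obs) - fit$rank, 1))
        hole <- miss[, tc]
        pred <- X[hole, , drop = FALSE] %*% beta
        cur[hole, tc] <- pred + rnorm(sum(hole), 0, sigma)
      }
    }
    acc <- acc + cur[, target_cols, drop = FALSE]
  }
  filled <- x
  for (tc in target_cols) {
    hole <- miss[, tc]
    filled[[tc]][hole] <- acc[hole, tc] / m
  }
  finish_imputation(features, filled, "multiple-imputation")
}

#' Median fill with test-not-performed flags
#'
#' Replaces each missing lab value with the column median of the fitting
#' split and adds, for every lab with any missingness, a binary flag
#' column (\code{miss_<lab>}) equal to 1 when the test was not performed
#' for that stay. The flags enter the downstream feature set.
#'
#' @inheritParams impute_multiple
#' @return An \code{imputation_result}; \code{flags} holds the flag columns.
#' @export
impute_median_with_flags <- function(features,
                                     fit_rows = seq_len(nrow(features$x))) {
  lab_cols <- impute_input(features)
  x <- features$x
  check_all_missing(x, lab_cols, fit_rows)
  filled <- x
  flags <- list()
  for (cc in lab_cols) {
    hole <- is.na(x[[cc]])
    if (!any(hole)) next
    med <- median(x[fit_rows, cc], na.rm = TRUE)
    filled[[cc]][hole] <- med
    flags[[sub("^worst_", "miss_", cc)]] <- as.integer(hole)
  }
  finish_imputation(features, filled, "median-flag",
                    flags = if (length(flags)) flags else NULL)
}

#' Group-mean fill by severity-score decile
#'
#' Ranks stays by their APACHE IVa score on the fitting split and forms
#' \code{n_groups} equal-sized groups (rank deciles by default; ties broken
#' by stable row order; sizes equal up to remainder). Each missing lab cell
#' is replaced by its group's observed mean on the fitting split; a group
#' with no observed values for some lab falls back to the overall fitting
#' mean, with a message.
#'
#' @inheritParams impute_multiple
#' @param apache_scores Numeric severity score per row of the matrix.
#' @param n_groups Number of score groups. Default 10.
#' @return An \code{imputation_result}.
#' @export
impute_group_mean <- function(features, apache_scores, n_groups = 10,
                              fit_rows = seq_len(nrow(features$x))) {
  lab_cols <- impute_input(features)
  x <- features$x
  if (length(apache_scores) != nrow(x)) {
    stop("apache_scores must have one value per row")
  }
  if (any(is.na(apache_scores))) stop("apache scores must be available for all rows")
  check_all_missing(x, lab_cols, fit_rows)

  fit_mask <- rep(FALSE, nrow(x)); fit_mask[fit_rows] <- TRUE
  # group boundaries from fitting-split score ranks; applied to all rows
  qs <- quantile(apache_scores[fit_mask],
                 probs = seq_len(n_groups - 1) / n_groups, type = 1)
  grp <- findInterval(apache_scores, unique(qs), left.open = TRUE) + 1L
  # within the fitting split, rebalance ties so groups are equal-sized up
  # to remainder: rank with stable order, then cut into blocks
  rk <- rank(apache_scores[fit_mask], ties.method = "first")
  grp_fit <- ceiling(rk * n_groups / sum(fit_mask))
  grp[fit_mask] <- grp_fit

  filled <- x
  for (cc in lab_cols) {
    hole <- is.na(x[[cc]])
    if (!any(hole)) next
    overall <- mean(x[fit_mask, cc], na.rm = TRUE)
    gm <- tapply(x[fit_mask & !hole, cc], grp[fit_mask & !hole], mean)
    means <- rep(overall, n_groups)
    means[as.integer(names(gm))] <- as.numeric(gm)
    empty <- setdiff(seq_len(n_groups), as.integer(names(gm)))
    if (length(empty)) {
      message("lab ", cc, ": group(s) ", paste(empty, collapse = ","),
              " had no observed values; using overall mean")
    }
    filled[[cc]][hole] <- means[pmin(pmax(grp[hole], 1L), n_groups)]
  }
  res <- finish_imputation(features, filled, "group-mean")
  res$groups <- grp
  res
}
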