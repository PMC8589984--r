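# Lasso-logistic feature selection with cross-validated penalty rules and
# unpenalized refit for inference.

#' Model configuration for error-prediction fits
#'
#' @param response Which score error to model: \code{"type1"} (false
#'   positive, fit among stays predicted to die) or \code{"type2"} (false
#'   negative, fit among stays predicted to survive).
#' @param include_arc Include the ARC statistic as a candidate predictor.
#' @param penalty_rule \code{"one_se"}: largest penalty whose CV deviance
#'   is within one standard error of the minimum; \code{"ci95"}: largest
#'   penalty within the 95\% confidence interval of the minimum. The ci95
#'   rule always yields a penalty at least as large (a model at most as
#'   big) as one_se.
#' @param cv_folds Number of cross-validation folds. Default 10.
#' @param lambda_grid Optional decreasing positive penalty grid; by default
#'   100 log-spaced values from the all-zero penalty down four decades.
#' @param adasyn List: \code{enabled}, target minority/majority
#'   \code{ratio}, neighbours \code{k}. Applied inside each training fold
#'   (and to the final training sample), never to validation data.
#' @param seed Integer seed for folds and oversampling.
#' @return A list of class \code{model_config}.
#' @export
model_config <- function(response = c("type1", "type2"),
                         include_arc = TRUE,
                         penalty_rule = c("one_se", "ci95"),
                         cv_folds = 10,
                         lambda_grid = NULL,
                         adasyn = list(enabled = TRUE, ratio = 1, k = 5),
                         seed = 1L) {
  response <- match.arg(response)
  penalty_rule <- match.arg(penalty_rule)
  if (cv_folds < 2) stop("cv_folds must be at least 2")
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0) || any(diff(lambda_grid) >= 0)) {
      stop("lambda_grid must be positive and strictly decreasing")
    }
  }
  adasyn <- utils::modifyList(list(enabled = TRUE, ratio = 1, k = 5), adasyn)
  structure(list(response = response, include_arc = include_arc,
                 penalty_rule = penalty_rule, cv_folds = cv_folds,
                 lambda_grid = lambda_grid, adasyn = adasyn,
                 seed = as.integer(seed)),
            class = "model_config")
}

# stratified fold assignment; every fold gets both classes when possible
stratified_folds <- function(y, nfolds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  folds
}

binomial_deviance <- function(p, y) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Lasso-logistic selection with cross-validated penalty choice
#'
#' Fits an L1-penalized logistic regression path (via \pkg{glmnet}) and
#' selects the penalty by stratified k-fold cross-validation on binomial
#' deviance. When ADASYN is enabled, oversampling is applied inside each
#' training fold only, so validation deviance is always measured on
#' original data. The penalty rule (one-SE or 95\%-CI, see
#' \code{\link{model_config}}) picks the final penalty; the selected
#' feature set is the non-zero coefficients of a final path fit (on the
#' full, optionally oversampled, sample) at that penalty.
#'
#' @param x Numeric feature matrix with named columns, standardized.
#' @param y Binary 0/1 response.
#' @param config A \code{\link{model_config}}.
#' @return A list of class \code{lasso_cv} with the chosen \code{lambda},
#'   \code{selected} feature names, \code{lasso_coef} (named non-zero
#'   coefficients, intercept excluded), the CV table (\code{lambda},
#'   \code{cvm}, \code{cvsd}), \code{lambda_min}, and the augmented sample
#'   (\code{x_fit}, \code{y_fit}) used for the final fit.
#' @export
fit_lasso_cv <- function(x, y, config = model_config()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("response must contain both classes")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  augment <- function(xa, ya, seed) {
    if (config$adasyn$enabled) {
      out <- adasyn_oversample(xa, ya, ratio = config$adasyn$ratio,
                               k = config$adasyn$k, seed = seed)
      list(x = out$x, y = out$y)
    } else list(x = xa, y = ya)
  }

  full <- augment(x, y, config$seed)
  init <- glmnet::glmnet(full$x, full$y, family = "binomial",
                         lambda = config$lambda_grid, nlambda = 100,
                         lambda.min.ratio = 1e-4, standardize = FALSE)
  lambda <- init$lambda

  folds <- stratified_folds(y, config$cv_folds)
  fold_dev <- matrix(NA_real_, config$cv_folds, length(lambda))
  for (f in seq_len(config$cv_folds)) {
    tr <- folds != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
      stop("degenerate fold: a fold lacks both classes; use fewer folds")
    }
    aug <- augment(x[tr, , drop = FALSE], y[tr], config$seed + f)
    fit <- glmnet::glmnet(aug$x, aug$y, family = "binomial", lambda = lambda,
                          standardize = FALSE)
    # models trained on a rebalanced sample carry its artificial base rate;
    # remove the prior log-odds shift before scoring the (original-
    # distribution) validation fold
    shift <- qlogis(mean(aug$y)) - qlogis(mean(y[tr]))
    eta <- predict(fit, newx = x[!tr, , drop = FALSE], s = lambda,
                   type = "link")
    p <- plogis(eta - shift)
    fold_dev[f, ] <- apply(p, 2, binomial_deviance, y = y[!tr])
  }
  cvm <- colMeans(fold_dev)
  cvsd <- apply(fold_dev, 2, sd) / sqrt(config$cv_folds)

  i_min <- which.min(cvm)
  mult <- if (config$penalty_rule == "one_se") 1 else 1.96
  ok <- cvm <= cvm[i_min] + mult * cvsd[i_min]
  i_sel <- which(ok)[1]  # lambda decreasing: first index = largest penalty
  lam <- lambda[i_sel]

  beta <- as.matrix(coef(init, s = lam))[, 1]
  beta <- beta[setdiff(names(beta), "(Intercept)")]
  selected <- names(beta)[beta != 0]

  structure(list(lambda = lam, lambda_min = lambda[i_min],
                 penalty_rule = config$penalty_rule,
                 selected = selected, lasso_coef = beta[selected],
                 cv = data.frame(lambda = lambda, cvm = cvm, cvsd = cvsd),
                 x_fit = full$x, y_fit = full$y),
            class = "lasso_cv")
}

#' @export
print.lasso_cv <- function(x, ...) {
  cat(sprintf("<lasso_cv> rule %s: lambda %.5f (min %.5f), %d feature(s) selected\n",
              x$penalty_rule, x$lambda, x$lambda_min, length(x$selected)))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# ridge-stabilized logistic fit by Newton iterations; returns coef and SE
ridge_logistic <- function(X, y, lambda = 1e-4) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)))  # intercept unpenalized
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + 2 * pen
    g <- crossprod(X, y - mu) - 2 * pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  Hinv <- solve(crossprod(X, X * plogis(drop(X %*% beta)) *
                            (1 - plogis(drop(X %*% beta)))) + 2 * pen)
  list(coef = beta, se = sqrt(diag(Hinv)))
}

#' Unpenalized logistic refit of the Lasso-selected features
#'
#' Ordinary maximum-likelihood logistic regression on the selected feature
#' set, yielding per-feature coefficient, standard error, absolute Z-ratio
#' (|coefficient / SE|) and Wald 95\% confidence interval (coefficient
#' +/- 1.96 SE), with rows sorted by Z-ratio descending. If the fit shows
#' signs of separation (non-convergence or runaway coefficients), a small
#' ridge stabilizer is used instead and the result is flagged.
#'
#' @param x Numeric matrix restricted to the selected features (named
#'   columns); must have at least one column.
#' @param y Binary 0/1 response.
#' @return A data frame of class \code{inference_table} with columns
#'   \code{feature}, \code{coefficient}, \code{se}, \code{z_ratio},
#'   \code{ci_low}, \code{ci_high}; attribute \code{stabilized} records
#'   whether the ridge fallback was used.
#' @export
refit_unpenalized <- function(x, y) {
  x <- as.matrix(x)
  if (ncol(x) == 0) {
    stop("selected feature set is empty; relax the penalty rule ",
         "(e.g. one_se instead of ci95) or lower the penalty")
  }
  df <- data.frame(y = as.integer(y), x, check.names = FALSE)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  cf <- summary(fit)$coefficients
  stabilized <- FALSE
  if (!fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE) ||
      any(is.na(coef(fit)))) {
    rl <- ridge_logistic(cbind(1, x), as.integer(y))
    cf <- cbind(Estimate = rl$coef, `Std. Error` = rl$se)
    rownames(cf) <- c("(Intercept)", colnames(x))
    stabilized <- TRUE
    message("separation detected; coefficients stabilized with a small ridge penalty")
  }
  intercept <- cf["(Intercept)", "Estimate"]
  cf <- cf[setdiff(rownames(cf), "(Intercept)"), , drop = FALSE]
  out <- data.frame(feature = rownames(cf),
                    coefficient = cf[, "Estimate"],
                    se = cf[, "Std. Error"],
                    z_ratio = abs(cf[, "Estimate"] / cf[, "Std. Error"]),
                    ci_low = cf[, "Estimate"] - 1.96 * cf[, "Std. Error"],
                    ci_high = cf[, "Estimate"] + 1.96 * cf[, "Std. Error"],
                    row.names = NULL)
  out <- out[order(-out$z_ratio), ]
  rownames(out) <- NULL
  class(out) <- c("inference_table", "data.frame")
  attr(out, "stabilized") <- stabilized
  attr(out, "intercept") <- unname(intercept)
  out
}

#' Fit one error-prediction model end to end
#'
#' Restricts the cohort to the relevant prediction side (Type I: stays the
#' score classifies as deaths; Type II: classified survivors),
#' standardizes features on the training rows of that side, optionally
#' appends ARC, runs \code{\link{fit_lasso_cv}} on the training rows,
#' refits the selected set without penalty on the same (oversampled)
#' sample, and evaluates on the holdout rows at a 0.5 probability
#' threshold.
#'
#' @param features A completed \code{feature_matrix} (no missing lab
#'   cells; see the \code{impute_*} functions).
#' @param labels An \code{error_labels} data frame aligned with the
#'   feature matrix by \code{stay_id}.
#' @param train_ids,holdout_ids Stay ids of the training and holdout
#'   splits (see \code{\link{split_holdout}}).
#' @param config A \code{\link{model_config}}.
#' @return A list of class \code{error_model_fit}: \code{config},
#'   \code{selection} (\code{lasso_cv}), \code{inference}
#'   (\code{inference_table}), \code{metrics} (holdout
#'   \code{\link{confusion_metrics}} report with ranking metrics),
#'   \code{n_train}, \code{n_holdout}.
#' @export
fit_error_model <- function(features, labels, train_ids, holdout_ids,
                            config = model_config()) {
  if (!inherits(features, "feature_matrix")) {
    stop("features must be a feature_matrix; run an impute_* function first")
  }
  if (anyNA(features$x[intersect(features$lab_cols, names(features$x))])) {
    stop("feature matrix still has missing lab cells; impute first")
  }
  if (!"stay_id" %in% names(labels)) stop("labels must carry stay_id")
  side_val <- if (config$response == "type1") 1L else 0L
  lab_side <- labels[labels$predicted_death == side_val, ]
  keep_ids <- intersect(features$x$stay_id, lab_side$stay_id)
  xdf <- features$x[match(keep_ids, features$x$stay_id), ]
  ll <- lab_side[match(keep_ids, lab_side$stay_id), ]
  y <- if (config$response == "type1") ll$type1 else ll$type2

  is_train <- keep_ids %in% train_ids
  is_hold <- keep_ids %in% holdout_ids
  if (!any(is_train) || !any(is_hold)) {
    stop("both training and holdout rows are required on the ",
         config$response, " side")
  }

  xnum <- xdf[setdiff(names(xdf), "stay_id")]
  if (config$include_arc) xnum$arc <- ll$arc
  std <- withCallingHandlers(
    standardize_features(xnum, fit_rows = which(is_train)),
    warning = function(w) invokeRestart("muffleWarning"))

  sel <- fit_lasso_cv(std$x[is_train, , drop = FALSE], y[is_train], config)
  inference <- NULL
  if (length(sel$selected)) {
    inference <- refit_unpenalized(sel$x_fit[, sel$selected, drop = FALSE],
                                   sel$y_fit)
  }

  # holdout evaluation with the refit model (0.5 probability threshold)
  metrics <- NULL
  if (length(sel$selected)) {
    beta <- setNames(inference$coefficient, inference$feature)[sel$selected]
    Xh <- std$x[is_hold, sel$selected, drop = FALSE]
    ph <- plogis(attr(inference, "intercept") + drop(Xh %*% beta))
    yh <- y[is_hold]
    metrics <- confusion_metrics(yh, as.integer(ph > 0.5))
    if (length(unique(yh)) == 2) {
      rk <- ranking_metrics(ph, yh)
      metrics$auroc <- rk$auroc
      metrics$auprc <- rk$auprc
    }
    metrics$pop_error_rate <- 100 * mean(yh)
  }

  structure(list(config = config, selection = sel, inference = inference,
                 metrics = metrics,
                 standardization = list(center = std$center,
                                        scale = std$scale,
                                        dropped = std$dropped),
                 n_train = sum(is_train), n_holdout = sum(is_hold)),
            class = "error_model_fit")
}

#' @export
print.error_model_fit <- function(x, ...) {
  cat(sprintf("<error_model_fit> %s (%s ARC), rule %s\n",
              x$config$response,
              if (x$config$include_arc) "with" else "without",
              x$config$penalty_rule))
  cat(sprintf("  n train/holdout: %d/%d; lambda %.5f; %d feature(s)\n",
              x$n_train, x$n_holdout, x$selection$lambda,
              length(x$selection$selected)))
  if (!is.null(x$inference)) {
    print(as.data.frame(lapply(x$inference, function(v)
      if (is.numeric(v)) round(v, 4) else v)))
  }
  if (!is.null(x$metrics)) {
    cat(sprintf("  holdout: AUROC %.4f AUPRC %.4f P %.4f R %.4f F %.4f acc %.4f\n",
                x$metrics$auroc, x$metrics$auprc, x$metrics$precision,
                x$metrics$recall, x$metrics$f_score, x$metrics$accuracy))
  }
  invisible(x)
}
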