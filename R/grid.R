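# End-to-end experiment grid: cutoffs x missing methods x responses x
# ARC inclusion, with per-cell resumability.

#' Specification of an experiment grid
#'
#' @param cutoffs Numeric cutoffs to audit; the string \code{"calibrated"}
#'   may be included to calibrate a cutoff against the cohort's observed
#'   mortality (see \code{\link{calibrate_cutoff}}). Default: 0.10, the
#'   calibrated value, and 0.50.
#' @param missing_methods Subset of \code{c("mi", "median_flag",
#'   "group_mean")}.
#' @param responses Subset of \code{c("type1", "type2")}.
#' @param include_arc Logical vector; each value is one grid axis level.
#' @param penalty_rule Penalty rule passed to \code{\link{model_config}}.
#' @param replications Number of reseeded replications per cell. Default 1
#'   (use \code{\link{replicate_selection}} for the five-replication
#'   stability check).
#' @param holdout_fraction Holdout fraction. Default 0.2.
#' @param seed Master seed.
#' @return A list of class \code{run_spec}.
#' @export
run_spec <- function(cutoffs = c(0.10, "calibrated", 0.50),
                     missing_methods = c("mi", "median_flag", "group_mean"),
                     responses = c("type1", "type2"),
                     include_arc = c(TRUE, FALSE),
                     penalty_rule = "one_se",
                     replications = 1,
                     holdout_fraction = 0.2,
                     seed = 1L) {
  missing_methods <- match.arg(missing_methods,
                               c("mi", "median_flag", "group_mean"),
                               several.ok = TRUE)
  responses <- match.arg(responses, c("type1", "type2"), several.ok = TRUE)
  if (!length(cutoffs) || !length(include_arc)) stop("grid axes must be non-empty")
  if (replications < 1) stop("replications must be at least 1")
  structure(list(cutoffs = cutoffs, missing_methods = missing_methods,
                 responses = responses, include_arc = include_arc,
                 penalty_rule = penalty_rule,
                 replications = as.integer(replications),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "run_spec")
}

impute_by_method <- function(features, method, stays, train_rows, seed) {
  switch(method,
    mi = impute_multiple(features, m = 10, seed = seed, fit_rows = train_rows),
    median_flag = impute_median_with_flags(features, fit_rows = train_rows),
    group_mean = impute_group_mean(
      features, stays$apache_score[match(features$x$stay_id, stays$stay_id)],
      fit_rows = train_rows),
    stop("unknown missing method: ", method))
}

cell_tag <- function(cutoff, method, response, arc, rep) {
  sprintf("cut%s_%s_%s_arc%d_rep%d",
          gsub("\\.", "p", format(cutoff, digits = 4)), method, response,
          as.integer(arc), rep)
}

#' Run the full experiment grid on a built cohort
#'
#' For every combination of cutoff, missing-data method, response and ARC
#' inclusion (times replications), labels the score's errors, imputes,
#' fits the selection + refit pipeline and evaluates on the holdout. Each
#' completed cell is written as JSON under \code{out_dir} (keyed by its
#' grid tag, seed and config hash); existing cell files are not recomputed,
#' making an interrupted grid resumable. A cell that fails is recorded
#' with its error message and the grid continues.
#'
#' @param spec A \code{\link{run_spec}}.
#' @param tables A filtered \code{raw_tables} cohort (after
#'   \code{\link{apply_exclusions}}).
#' @param out_dir Directory for per-cell JSON artifacts; \code{NULL}
#'   disables persistence (no resumability).
#' @return A list of class \code{grid_result}: \code{fits} (named list of
#'   \code{error_model_fit} or error records), \code{metrics} (one data
#'   frame row per successful cell, shaped like a performance-metrics
#'   table), \code{spec}.
#' @export
run_grid <- function(spec, tables, out_dir = NULL) {
  if (!inherits(spec, "run_spec")) stop("spec must be a run_spec")
  if (!inherits(tables, "raw_tables")) stop("tables must be a raw_tables object")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stays <- tables$stays
  split <- split_holdout(stays$stay_id, spec$holdout_fraction, spec$seed)
  features <- build_feature_matrix(tables)
  train_rows <- which(features$x$stay_id %in% split$train)
  obs_rate <- mean(stays$died[stays$stay_id %in% split$train])

  cutoffs <- lapply(spec$cutoffs, function(cc) {
    if (identical(cc, "calibrated")) {
      calibrate_cutoff(stays$apache_prob[stays$stay_id %in% split$train],
                       obs_rate)$value
    } else as.numeric(cc)
  })

  fits <- list()
  metrics <- NULL
  for (cutoff in cutoffs) {
    labels <- label_errors(stays$apache_prob, cutoff, stays$died,
                           stay_id = stays$stay_id)
    for (method in spec$missing_methods) {
      imp <- impute_by_method(features, method, stays, train_rows, spec$seed)
      for (response in spec$responses) {
        for (arc in spec$include_arc) {
          for (rep in seq_len(spec$replications)) {
            tag <- cell_tag(cutoff, method, response, arc, rep)
            cell_file <- if (!is.null(out_dir)) {
              file.path(out_dir, paste0(tag, ".json"))
            } else NULL
            if (!is.null(cell_file) && file.exists(cell_file)) {
              fits[[tag]] <- jsonlite::read_json(cell_file,
                                                 simplifyVector = TRUE)
              fits[[tag]]$resumed <- TRUE
            } else {
              cfg <- model_config(response = response, include_arc = arc,
                                  penalty_rule = spec$penalty_rule,
                                  seed = spec$seed + 1000L * rep)
              fit <- tryCatch(
                fit_error_model(imp$features, labels, split$train,
                                split$holdout, cfg),
                error = function(e) structure(
                  list(error = conditionMessage(e)), class = "cell_error"))
              if (inherits(fit, "cell_error")) {
                fits[[tag]] <- list(tag = tag, error = fit$error)
              } else {
                fits[[tag]] <- fit
                m <- fit$metrics
                cell <- list(tag = tag, cutoff = cutoff, method = method,
                             response = response, include_arc = arc,
                             rep = rep, seed = cfg$seed,
                             lambda = fit$selection$lambda,
                             selected = fit$selection$selected,
                             inference = fit$inference,
                             metrics = m[c("pop_error_rate", "auroc",
                                           "auprc", "precision", "recall",
                                           "f_score", "accuracy")])
                if (!is.null(cell_file)) {
                  jsonlite::write_json(
                    c(cell, list(config_hash = cell_config_hash(cell))),
                    cell_file, auto_unbox = TRUE, digits = NA, force = TRUE)
                }
              }
            }
            f <- fits[[tag]]
            if (is.null(f$error)) {
              m <- f$metrics
              pick <- function(k) {
                v <- m[[k]]
                if (is.null(v) || !length(v)) NA_real_ else as.numeric(v)
              }
              metrics <- rbind(metrics, data.frame(
                cutoff = cutoff, method = method, response = response,
                include_arc = arc, rep = rep,
                pop_error_rate = pick("pop_error_rate"),
                auroc = pick("auroc"), auprc = pick("auprc"),
                precision = pick("precision"), recall = pick("recall"),
                f_score = pick("f_score"), accuracy = pick("accuracy")))
            }
          }
        }
      }
    }
  }
  structure(list(fits = fits, metrics = metrics, spec = spec,
                 cutoffs = unlist(cutoffs)),
            class = "grid_result")
}

# small stable hash of a cell config (dependency-free)
cell_config_hash <- function(obj) {
  s <- paste(deparse(obj[c("tag", "cutoff", "method", "response",
                           "include_arc", "rep", "seed")]), collapse = "")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9
}

#' @export
print.grid_result <- function(x, ...) {
  ok <- sum(vapply(x$fits, function(f) is.null(f$error), logical(1)))
  cat(sprintf("<grid_result> %d cell(s), %d successful\n", length(x$fits), ok))
  if (!is.null(x$metrics)) {
    print(as.data.frame(lapply(x$metrics, function(v)
      if (is.numeric(v)) round(v, 4) else v)))
  }
  invisible(x)
}

#' Selected-feature stability across reseeded replications
#'
#' Re-runs the selection pipeline with \code{n_reps} different seeds on
#' the same data and reports the selected set of each replication plus
#' whether all sets are identical.
#'
#' @param features Completed \code{feature_matrix}.
#' @param labels \code{error_labels} with \code{stay_id}.
#' @param train_ids,holdout_ids Split id vectors.
#' @param response,include_arc,penalty_rule Passed to
#'   \code{\link{model_config}}.
#' @param n_reps Number of replications. Default 5.
#' @param seed Base seed; replication r uses \code{seed + r}.
#' @return List with \code{sets} (list of selected-name vectors) and
#'   \code{identical} (logical).
#' @export
replicate_selection <- function(features, labels, train_ids, holdout_ids,
                                response = "type1", include_arc = TRUE,
                                penalty_rule = "one_se", n_reps = 5,
                                seed = 1L) {
  sets <- lapply(seq_len(n_reps), function(r) {
    cfg <- model_config(response = response, include_arc = include_arc,
                        penalty_rule = penalty_rule, seed = seed + r)
    fit <- fit_error_model(features, labels, train_ids, holdout_ids, cfg)
    sort(fit$selection$selected)
  })
  list(sets = sets,
       identical = all(vapply(sets, identical, logical(1), y = sets[[1]])))
}
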