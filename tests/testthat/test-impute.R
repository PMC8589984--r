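test_that("median fill uses training medians and flags unmeasured tests", {
  fm <- make_feature_matrix(data.frame(worst_a = c(1, NA, 3),
                                       worst_b = c(4, 5, 6),
                                       mean_hr = c(80, 90, 100)),
                            lab_cols = c("worst_a", "worst_b"))
  res <- impute_median_with_flags(fm)
  expect_equal(res$features$x$worst_a, c(1, 2, 3))
  expect_equal(res$features$x$miss_a, c(0L, 1L, 0L))
  expect_false("miss_b" %in% names(res$features$x))  # no missing, no flag
  expect_equal(unname(res$ledger), c(1L, 0L))
  # medians come from the fitting rows, applied to all rows
  fm2 <- make_feature_matrix(data.frame(worst_a = c(1, 3, NA, 100),
                                        mean_hr = 1:4),
                             lab_cols = "worst_a")
  res2 <- impute_median_with_flags(fm2, fit_rows = 1:2)
  expect_equal(res2$features$x$worst_a[3], 2)
  expect_error(
    impute_median_with_flags(make_feature_matrix(
      data.frame(worst_a = c(NA_real_, NA_real_), mean_hr = c(1, 2)),
      lab_cols = "worst_a")),
    "entirely missing")
})

test_that("group-mean fill forms equal-sized score deciles and is exact on planted groups", {
  # 20 rows, 10 groups: every group has size 2
  set.seed(61)
  x <- data.frame(worst_a = rep(NA_real_, 20), mean_hr = 1:20)
  scores <- sample(1:100, 20)
  # planted construction: one observed, one missing per group; zero noise
  grp_of <- ceiling(rank(scores, ties.method = "first") * 10 / 20)
  x$worst_a <- as.numeric(grp_of)          # value == group mean exactly
  ord <- order(scores)
  x$worst_a[ord[seq(1, 20, by = 2)]] <- NA # knock out one cell per group
  fm <- make_feature_matrix(x, lab_cols = "worst_a")
  res <- impute_group_mean(fm, scores, n_groups = 10)
  expect_equal(as.integer(table(res$groups)), rep(2L, 10))
  expect_equal(res$features$x$worst_a, as.numeric(grp_of))  # exact recovery
  # constant column: any fill is that constant
  fmc <- make_feature_matrix(data.frame(worst_a = c(7, 7, NA, 7),
                                        mean_hr = 1:4),
                             lab_cols = "worst_a")
  expect_equal(impute_group_mean(fmc, c(10, 20, 30, 40),
                                 n_groups = 2)$features$x$worst_a,
               rep(7, 4))
  expect_error(impute_group_mean(fm, scores[-1]), "one value per row")
  expect_error(impute_group_mean(fm, replace(scores, 1, NA)), "available")
})

test_that("a score group with no observed values falls back to the overall mean", {
  x <- data.frame(worst_a = c(1, 2, NA, NA), mean_hr = 1:4)
  fm <- make_feature_matrix(x, lab_cols = "worst_a")
  expect_message(res <- impute_group_mean(fm, c(1, 2, 9, 10), n_groups = 2),
                 "overall mean")
  expect_equal(res$features$x$worst_a[3:4], c(1.5, 1.5))
})

test_that("multiple imputation is deterministic, pools m completions, and beats a median fill under MCAR", {
  # no missing cells: identity
  fm0 <- make_feature_matrix(data.frame(worst_a = c(1, 2), mean_hr = c(3, 4)),
                             lab_cols = "worst_a")
  expect_equal(impute_multiple(fm0, seed = 1)$features$x, fm0$x)
  expect_error(impute_multiple(fm0, m = 1), "at least 2")

  # correlated labs with 20% MCAR deletion
  set.seed(42)
  n <- 5000
  z <- rnorm(n)
  truth <- data.frame(worst_a = z + rnorm(n, 0, 0.3),
                      worst_b = 2 * z + rnorm(n, 0, 0.3),
                      mean_hr = z + rnorm(n, 0, 0.3))
  holes <- sample(n, 0.2 * n)
  x <- truth
  x$worst_a[holes] <- NA
  fm <- make_feature_matrix(x, lab_cols = c("worst_a", "worst_b"))
  r1 <- impute_multiple(fm, m = 10, seed = 9)
  r2 <- impute_multiple(fm, m = 10, seed = 9)
  expect_identical(r1$features$x, r2$features$x)
  expect_equal(unname(r1$ledger["worst_a"]), length(holes))
  # observed cells untouched
  expect_equal(r1$features$x$worst_a[-holes], truth$worst_a[-holes])
  rmse_mi <- sqrt(mean((r1$features$x$worst_a[holes] - truth$worst_a[holes])^2))
  med <- median(x$worst_a, na.rm = TRUE)
  rmse_med <- sqrt(mean((med - truth$worst_a[holes])^2))
  expect_lt(rmse_mi, rmse_med)
  expect_error(impute_multiple(make_feature_matrix(
    data.frame(worst_a = rep(NA_real_, 3), mean_hr = 1:3),
    lab_cols = "worst_a"), seed = 1), "entirely missing")
})

test_that("all three strategies leave observed cells untouched and fill every hole", {
  bc <- built_cohort(2000, seed = 301)
  fm <- bc$features
  obs_mask <- !is.na(as.matrix(fm$x[fm$lab_cols]))
  scores <- bc$stays$apache_score[match(fm$x$stay_id, bc$stays$stay_id)]
  results <- list(
    mi = impute_multiple(fm, m = 3, seed = 5, fit_rows = bc$train_rows),
    med = impute_median_with_flags(fm, fit_rows = bc$train_rows),
    grp = impute_group_mean(fm, scores, fit_rows = bc$train_rows))
  orig <- as.matrix(fm$x[fm$lab_cols])
  for (nm in names(results)) {
    filled <- as.matrix(results[[nm]]$features$x[fm$lab_cols])
    expect_false(anyNA(filled), label = nm)
    expect_equal(filled[obs_mask], orig[obs_mask], label = nm)
    expect_equal(unname(results[[nm]]$ledger),
                 unname(colSums(!obs_mask)), label = nm)
  }
})
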