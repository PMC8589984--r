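test_that("confusion metrics match hand arithmetic on a fixture", {
  truth <-     c(1, 1, 0, 1, 1, 0, 0, 0, 0, 0)
  predicted <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)  # TP 2, FP 1, FN 2, TN 5
  m <- confusion_metrics(truth, predicted)
  expect_equal(m[c("tp", "fp", "fn", "tn")], list(tp = 2L, fp = 1L, fn = 2L,
                                                  tn = 5L), ignore_attr = TRUE)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 1 / 2)
  expect_equal(m$accuracy, 0.7)
  perfect <- confusion_metrics(truth, truth)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f_score,
                 perfect$accuracy), rep(1, 4))
  expect_warning(none <- confusion_metrics(truth, rep(0, 10)),
                 "precision undefined")
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  expect_error(confusion_metrics(1, c(1, 0)), "equal length")
})

test_that("the F-score is the harmonic mean and symmetric", {
  expect_equal(f_score(0.5, 0.5), 0.5)
  for (v in c(0.1, 0.42, 0.9)) expect_equal(f_score(v, v), v)
  expect_equal(f_score(0.6, 0.3), 2 * 0.6 * 0.3 / 0.9)
  # printed precision/recall pairs reproduce the published F within the
  # propagation bound of their own 4-decimal rounding
  expect_lt(abs(f_score(0.2436, 0.2705) - 0.2564), 1.5e-4)
  expect_lt(abs(f_score(0.6064, 0.8637) - 0.7126), 1.5e-4)
  expect_error(f_score(0, 0), "positive")
  expect_error(f_score(1.2, 0.5), "\\[0, 1\\]")
})

test_that("ranking metrics equal a brute-force threshold sweep and behave at the extremes", {
  brute <- function(scores, truth) {
    ths <- sort(unique(scores), decreasing = TRUE)
    prec <- rec <- numeric(length(ths))
    for (i in seq_along(ths)) {
      pred <- as.integer(scores >= ths[i])
      prec[i] <- sum(pred & truth) / sum(pred)
      rec[i] <- sum(pred & truth) / sum(truth)
    }
    sum(diff(c(0, rec)) * prec)
  }
  # 6-point fixture with a tie
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  truth <- c(1, 0, 1, 1, 0, 0)
  rm <- ranking_metrics(scores, truth)
  expect_equal(rm$auprc, brute(scores, truth))
  set.seed(8)
  for (i in 1:5) {
    sc <- round(runif(30), 1)  # ties guaranteed
    tr <- rbinom(30, 1, 0.4)
    if (length(unique(tr)) < 2) next
    expect_equal(ranking_metrics(sc, tr)$auprc, brute(sc, tr))
  }
  expect_equal(ranking_metrics(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auroc, 1)
  set.seed(9)
  null <- ranking_metrics(runif(10000), rbinom(10000, 1, 0.3))
  expect_lt(abs(null$auroc - 0.5), 0.02)
  expect_error(ranking_metrics(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC agrees with an independent implementation and is rank-invariant", {
  skip_if_not_installed("pROC")
  set.seed(10)
  scores <- rnorm(200)
  truth <- rbinom(200, 1, plogis(scores))
  ours <- ranking_metrics(scores, truth)$auroc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_equal(ranking_metrics(exp(3 * scores), truth)$auroc, ours)
})

test_that("hospital calibration computes per-hospital points and size classes", {
  stays <- data.frame(hospital_id = rep(1, 10), beds = 250,
                      apache_prob = rep(0.2, 10),
                      died = c(1, rep(0, 9)))
  hc <- hospital_calibration(stays)
  expect_equal(hc$observed_mortality, 0.1)
  expect_equal(hc$predicted_mortality, 0.2)
  expect_true(hc$below_diagonal)
  expect_equal(hc$size_class, "medium")   # 250 beds
  classes <- hospital_calibration(data.frame(
    hospital_id = 1:4, beds = c(99, 100, 499, 500),
    apache_prob = 0.1, died = 0))$size_class
  expect_equal(classes, c("very_small", "small", "medium", "large"))
  expect_error(hospital_calibration(data.frame(hospital_id = 1)), "beds")
})

test_that("patient-by-lab accounting tallies zero/one/multiple measurement combinations", {
  stays <- data.frame(stay_id = 1:3)
  labs <- data.frame(stay_id = c(1, 1, 2),
                     lab = c("lactate", "lactate", "creatinine"),
                     offset_hours = c(1, 2, 3), value = c(2, 3, 1))
  cat2 <- lab_catalog()[lab_catalog()$lab %in% c("lactate", "creatinine"), ]
  tabs <- tiny_tables(stays, labs = labs)
  acct <- lab_measurement_accounting(tabs, catalog = cat2)
  # 6 combinations: 1 with two measurements, 1 with one, 4 with none
  expect_equal(acct$count, c(4, 1, 1))
  expect_equal(acct$percent, c(66.7, 16.7, 16.7))
  expect_equal(attr(acct, "total"), 6)
  direct <- lab_measurement_accounting(counts = c(none = 2, one = 1,
                                                  two_plus = 1))
  expect_equal(direct$percent, c(50, 25, 25))
})
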