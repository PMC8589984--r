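test_that("worst-value rules pick the clinically worst measurement", {
  expect_equal(worst_lab_value(c(1.2, 3.1, 5.0), lab_rule("lactate", "max")), 5.0)
  expect_equal(worst_lab_value(c(9.0, 7.2), lab_rule("ph", "min")), 7.2)
  # deviation rule: 150 is 10 above range, 65 only 5 below
  glu <- lab_rule("glucose", "deviant", low = 70, high = 140)
  expect_equal(worst_lab_value(c(65, 150), glu), 150)
  expect_equal(worst_lab_value(c(60, 145), glu), 60)
  # equal deviation ties go to the higher value
  expect_equal(worst_lab_value(c(60, 150), glu), 150)
  # conditional rule: minimum only when something fell below the lower limit
  wbc <- lab_rule("wbc", "conditional_min", low = 4, high = 11)
  expect_equal(worst_lab_value(c(3.0, 12.0), wbc), 3.0)
  expect_equal(worst_lab_value(c(5.0, 12.0), wbc), 12.0)
})

test_that("worst-value operators are permutation-invariant and handle degenerate input", {
  rules <- list(lab_rule("a", "min"), lab_rule("a", "max"),
                lab_rule("a", "deviant", 10, 20),
                lab_rule("a", "conditional_min", 10, 20))
  set.seed(99)
  for (r in rules) {
    for (i in 1:5) {
      v <- runif(7, 5, 25)
      expect_equal(worst_lab_value(sample(v), r), worst_lab_value(v, r))
    }
    expect_equal(worst_lab_value(12.3, r), 12.3)  # singleton is its own worst
    expect_true(is.na(worst_lab_value(numeric(0), r)))
  }
  expect_error(lab_rule("a", "deviant"), "reference range")
  expect_error(lab_rule("a", "deviant", 5, 2), "low < high")
})

test_that("vital summaries give mean and both extremes", {
  s <- summarize_vitals(c(98, 92, 95))
  expect_equal(unname(s), c(95, 92, 98))
  expect_equal(unname(summarize_vitals(88)), c(88, 88, 88))
  expect_true(all(is.na(summarize_vitals(numeric(0)))))
})

test_that("diagnosis text maps to exactly one of 21 categories with ACS baseline", {
  enc <- encode_admission_dx(c("Sepsis, pulmonary",
                               "Acute coronary syndrome / myocardial infarction",
                               "complete gibberish 123"))
  expect_equal(enc$category, c("sepsis", "acs", "other"))
  expect_equal(ncol(enc$indicators), 20)
  expect_equal(unname(enc$indicators[1, "dx_sepsis"]), 1)
  expect_equal(sum(enc$indicators[1, ]), 1)
  expect_equal(sum(enc$indicators[2, ]), 0)   # ACS is the baseline
  expect_equal(unname(enc$indicators[3, "dx_other"]), 1)
  # every generator phrase maps back to its own category
  phr <- apacheaudit:::dx_phrases()
  expect_equal(encode_admission_dx(unname(phr))$category, names(phr))
  # indicator row sums always in {0, 1}
  tabs <- generate_cohort(sim_config(n_stays = 400, n_hospitals = 5, seed = 8))
  enc2 <- encode_admission_dx(tabs$stays$admission_dx)
  expect_true(all(rowSums(enc2$indicators) %in% 0:1))
})

test_that("standardization fits on the training rows only and is idempotent there", {
  out <- standardize_features(data.frame(a = c(0, 2)))
  expect_equal(unname(out$x[, "a"]), c(-1, 1) / sqrt(2))  # sample SD (n-1)
  x <- data.frame(a = rnorm(50, 5, 2), b = runif(50))
  fit <- 1:30
  out <- standardize_features(x, fit_rows = fit)
  expect_equal(unname(colMeans(out$x[fit, ])), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(out$x[fit, ], 2, var)), c(1, 1), tolerance = 1e-9)
  # holdout rows transformed with training parameters, not their own
  expect_equal(out$x[31, "a"], (x$a[31] - mean(x$a[fit])) / sd(x$a[fit]),
               ignore_attr = TRUE)
  again <- standardize_features(as.data.frame(out$x[fit, ]))
  expect_equal(unname(again$x), unname(out$x[fit, ]), tolerance = 1e-9)
  expect_warning(standardize_features(data.frame(a = 1:5, k = rep(2, 5))),
                 "zero-variance")
})

test_that("the assembled feature matrix has complete non-lab columns and sane provenance", {
  bc <- built_cohort(2000, seed = 301)
  fm <- bc$features
  non_lab <- setdiff(names(fm$x), c("stay_id", fm$lab_cols))
  expect_false(anyNA(fm$x[non_lab]))
  expect_true(all(fm$lab_cols %in% names(fm$x)))
  expect_setequal(unique(unname(fm$provenance)),
                  c("vital_periodic", "vital_aperiodic", "lab", "treatment",
                    "careplan", "history", "demographic", "admission_dx"))
  # worst lactate column equals per-stay max of lactate measurements
  labs <- bc$tables$labs
  one <- labs[labs$lab == "lactate", ]
  id <- one$stay_id[1]
  expect_equal(fm$x$worst_lactate[fm$x$stay_id == id],
               max(one$value[one$stay_id == id]))
})
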