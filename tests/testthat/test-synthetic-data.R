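test_that("config validation rejects impossible cohorts and unknown plants", {
  expect_error(sim_config(n_stays = 0), "positive count")
  expect_error(sim_config(n_stays = 5, n_hospitals = 10), ">= n_hospitals")
  expect_error(sim_config(hospital_size_weights = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(sim_config(planted_effects = list(
    not_a_feature = list(type = "type2", beta = 1))), "unknown feature")
  expect_error(sim_config(lab_missingness = c(lactate = 1.2)), "\\[0, 1\\]")
  expect_error(sim_config(target_observed_mortality = 0.6,
                          overprediction_factor = 2), "< 1")
})

test_that("generation is deterministic under the master seed", {
  cfg <- sim_config(n_stays = 300, n_hospitals = 5, seed = 11)
  t1 <- generate_cohort(cfg)
  t2 <- generate_cohort(cfg)
  expect_identical(t1, t2)
  t3 <- generate_cohort(sim_config(n_stays = 300, n_hospitals = 5, seed = 12))
  expect_false(identical(t1$stays$died, t3$stays$died))
})

test_that("all child tables key into stays and offsets stay within 24h", {
  tabs <- generate_cohort(sim_config(n_stays = 500, n_hospitals = 8, seed = 3))
  ids <- tabs$stays$stay_id
  for (nm in c("labs", "vitals_periodic", "vitals_aperiodic", "treatments",
               "careplan", "history")) {
    expect_true(all(tabs[[nm]]$stay_id %in% ids), label = nm)
  }
  expect_true(all(tabs$labs$offset_hours >= 0 & tabs$labs$offset_hours <= 24))
  expect_true(all(tabs$vitals_periodic$offset_hours >= 0 &
                    tabs$vitals_periodic$offset_hours <= 24))
})

test_that("an identity distortion leaves the score calibrated and lab missingness hits its target", {
  cfg <- sim_config(n_stays = 10000, overprediction_factor = 1,
                    planted_effects = list(), seed = 21)
  tabs <- generate_cohort(cfg)
  obs <- mean(tabs$stays$died)
  pred <- mean(tabs$stays$apache_prob, na.rm = TRUE)
  mc_se <- sqrt(obs * (1 - obs) / nrow(tabs$stays))
  expect_lt(abs(pred - obs), 3 * mc_se)

  # per-lab absence matches configured rates (binomial interval at n=10,000)
  has_amylase <- tabs$stays$stay_id %in%
    tabs$labs$stay_id[tabs$labs$lab == "amylase"]
  expect_gt(mean(!has_amylase), 0.93)
  expect_lt(mean(!has_amylase), 0.97)
  has_creat <- tabs$stays$stay_id %in%
    tabs$labs$stay_id[tabs$labs$lab == "creatinine"]
  expect_lt(abs(mean(!has_creat) - 0.03), 0.01)
})

test_that("mean predicted over mean observed mortality approaches the overprediction factor", {
  tabs <- built_cohort(50000, seed = 501)$tables
  f <- sim_config()$overprediction_factor
  ratio <- mean(tabs$stays$apache_prob) / mean(tabs$stays$died)
  t <- mean(tabs$stays$died)
  mc_se <- f * sqrt((1 - t) / (t * nrow(tabs$stays)))
  expect_lt(abs(ratio - f), 3 * mc_se)
})

test_that("lab missingness is independent of the outcome", {
  tabs <- generate_cohort(sim_config(n_stays = 10000, seed = 31))
  miss <- !(tabs$stays$stay_id %in%
              tabs$labs$stay_id[tabs$labs$lab == "lactate"])
  fit <- glm(miss ~ tabs$stays$died, family = binomial())
  ci <- coef(summary(fit))[2, ]
  expect_true(abs(ci["Estimate"]) < 1.96 * ci["Std. Error"] * 1.5)
})

test_that("tables round-trip through CSV files", {
  tabs <- generate_cohort(sim_config(n_stays = 50, n_hospitals = 3, seed = 5))
  dir <- withr::local_tempdir()
  write_tables(tabs, dir)
  expect_true(file.exists(file.path(dir, "patient.csv")))
  back <- read_tables(dir)
  for (nm in names(unclass(tabs))) {
    expect_equal(back[[nm]], tabs[[nm]], tolerance = 1e-12,
                 ignore_attr = TRUE, label = nm)
  }
  # cardinality: one row per stay in patient.csv
  expect_equal(nrow(utils::read.csv(file.path(dir, "patient.csv"))),
               nrow(tabs$stays))
})

test_that("an empty cohort writes valid headers-only files", {
  tabs <- generate_cohort(sim_config(n_stays = 20, n_hospitals = 2, seed = 6))
  for (nm in names(unclass(tabs))) tabs[[nm]] <- tabs[[nm]][0, , drop = FALSE]
  dir <- withr::local_tempdir()
  write_tables(tabs, dir)
  back <- read_tables(dir)
  expect_equal(nrow(back$stays), 0)
  expect_setequal(names(back$labs), names(tabs$labs))
})
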