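sim_logistic <- function(n, p, beta = NULL, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- if (is.null(beta)) rep(0, n) else drop(x %*% beta)
  y <- rbinom(n, 1, plogis(-1 + eta))
  list(x = x, y = y)
}

test_that("pure-noise features are rarely selected under the one-SE rule", {
  hits <- vapply(1:10, function(s) {
    d <- sim_logistic(2000, 15, seed = 100 + s)
    fit <- fit_lasso_cv(d$x, d$y, model_config(cv_folds = 5, seed = s))
    length(fit$selected)
  }, numeric(1))
  expect_gte(sum(hits <= 2), 9)
})

test_that("a planted strong predictor is always selected and the penalty limit zeroes everything", {
  for (s in 1:10) {
    d <- sim_logistic(2000, 10, beta = c(1, rep(0, 9)), seed = 200 + s)
    fit <- fit_lasso_cv(d$x, d$y, model_config(cv_folds = 5, seed = s))
    expect_true("f1" %in% fit$selected, label = paste("seed", s))
  }
  d <- sim_logistic(500, 5, beta = c(1, rep(0, 4)), seed = 3)
  big <- fit_lasso_cv(d$x, d$y,
                      model_config(lambda_grid = c(100, 99), cv_folds = 5,
                                   seed = 1))
  expect_length(big$selected, 0)
})

test_that("the 95%-CI rule never selects more features than the one-SE rule", {
  for (s in 1:3) {
    d <- sim_logistic(1500, 12, beta = c(0.8, -0.6, 0.3, rep(0, 9)),
                      seed = 300 + s)
    one <- fit_lasso_cv(d$x, d$y,
                        model_config(penalty_rule = "one_se", cv_folds = 5,
                                     seed = s))
    ci <- fit_lasso_cv(d$x, d$y,
                       model_config(penalty_rule = "ci95", cv_folds = 5,
                                    seed = s))
    expect_gte(ci$lambda, one$lambda)
    expect_lte(length(ci$selected), length(one$selected))
  }
})

test_that("degenerate responses are rejected", {
  d <- sim_logistic(100, 3, seed = 4)
  expect_error(fit_lasso_cv(d$x, rep(1L, 100), model_config()),
               "both classes")
  expect_error(model_config(cv_folds = 1), "at least 2")
  expect_error(model_config(lambda_grid = c(1, 2)), "decreasing")
})

test_that("the unpenalized refit recovers the closed-form 2x2 log odds ratio", {
  # x=1: 40 deaths / 10 survivors; x=0: 20 / 20 -> odds ratio 4
  x <- matrix(rep(c(1, 1, 0, 0), c(40, 10, 20, 20)), ncol = 1,
              dimnames = list(NULL, "flag"))
  y <- rep(c(1, 0, 1, 0), c(40, 10, 20, 20))
  tab <- refit_unpenalized(x, y)
  expect_equal(tab$coefficient[tab$feature == "flag"], log(4),
               tolerance = 1e-6)
  # Wald machinery is definitional
  expect_equal(tab$ci_low, tab$coefficient - 1.96 * tab$se)
  expect_equal(tab$ci_high, tab$coefficient + 1.96 * tab$se)
  expect_equal(tab$z_ratio, abs(tab$coefficient / tab$se))
  expect_error(refit_unpenalized(x[, 0, drop = FALSE], y), "relax")
})

test_that("rows are sorted by Z-ratio and separation triggers the ridge stabilizer", {
  set.seed(11)
  x <- cbind(strong = rnorm(300), weak = rnorm(300))
  y <- rbinom(300, 1, plogis(2 * x[, "strong"] + 0.2 * x[, "weak"]))
  tab <- refit_unpenalized(x, y)
  expect_equal(tab$feature[1], "strong")
  expect_true(all(diff(tab$z_ratio) <= 0))
  # perfectly separated predictor
  xs <- cbind(sep = c(rep(-1, 20), rep(1, 20)))
  ys <- rep(c(0, 1), each = 20)
  expect_message(tab2 <- refit_unpenalized(xs, ys), "separation")
  expect_true(attr(tab2, "stabilized"))
  expect_true(is.finite(tab2$se[1]))
})
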