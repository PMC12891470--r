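test_that("ROC AUC equals the rank-sum statistic on hand-checked cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.2, 0.4, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0)), 0.5)
  set.seed(1)
  s <- runif(60); y <- rbinom(60, 1, 0.5)
  expect_equal(roc_auc(s, y), auc_oracle(s, y))
  skip_if_not_installed("pROC")
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
  expect_error(roc_auc(s, rep(1, 60)), class = "gaitstab_param_error")
})

test_that("threshold metrics and Brier score follow their definitions", {
  probs <- c(0.9, 0.6, 0.4, 0.1)
  y <- c(1, 0, 1, 0)
  expect_equal(brier_score(probs, y), mean((probs - y)^2))
  m <- classification_metrics(probs, y)
  expect_equal(unname(m["sensitivity"]), 0.5)   # one of two positives >= 0.5
  expect_equal(unname(m["specificity"]), 0.5)
  expect_equal(unname(m["f1"]), 0.5)
  r <- regression_metrics(c(1, 2, 3, 4), c(1.5, 2, 2.5, 4))
  expect_equal(unname(r["mse"]), mean(c(0.25, 0, 0.25, 0)))
  expect_equal(unname(r["rmse"]), sqrt(unname(r["mse"])))
  expect_equal(unname(r["r2"]), 1 - unname(r["mse"]) / var(c(1, 2, 3, 4)) * 4 / 3,
               tolerance = 1e-9)
})

test_that("every classifier separates a strongly separated toy problem", {
  set.seed(10)
  n <- 200
  y <- factor(rep(c("HC", "PwS"), each = n / 2))
  x <- as.data.frame(matrix(rnorm(n * 3), n) + outer(as.numeric(y) - 1, c(5, 5, 0)))
  names(x) <- c("a", "b", "c")
  tab <- cbind(data.frame(group = y), x)
  plan <- experiment_plan(n_repeats = 2, task = "classification",
                          augmenters = list(list(method = "none",
                                                 target_size = "balance100")))
  rep <- run_classification(tab, plan, preprocess = FALSE)
  expect_true(all(rep$summary$auc_mean >= 0.99))
  # report means must equal means of the stored raw values
  for (i in seq_len(nrow(rep$summary))) {
    sub <- rep$raw[rep$raw$model == rep$summary$model[i] &
                     rep$raw$augmenter == rep$summary$augmenter[i], ]
    expect_equal(rep$summary$auc_mean[i], mean(sub$auc))
  }
})

test_that("label permutation drives the AUC to chance", {
  coh <- simulate_classification_cohort(cohort_spec(), seed = 11)
  tab <- coh$features[c("group", stability_feature_names())]
  set.seed(99)
  tab$group <- sample(tab$group)
  plan <- experiment_plan(models = c("logistic", "rf"), n_repeats = 10,
                          task = "classification",
                          augmenters = list(list(method = "none",
                                                 target_size = "balance100")))
  rep <- suppressWarnings(run_classification(tab, plan))
  expect_true(all(abs(rep$summary$auc_mean - 0.5) <= 0.1))
})

test_that("regression harness recovers a perfect linear target exactly", {
  set.seed(3)
  x <- as.data.frame(matrix(rnorm(150 * 3), 150))
  x$target <- 2 * x$V1 - x$V2 + 0.5 * x$V3
  plan <- experiment_plan(models = "linear", n_repeats = 2, task = "regression")
  rep <- run_regression(x, "target", plan, preprocess = FALSE)
  expect_lt(abs(rep$summary$r2_mean - 1), 1e-6)
  # an unrelated target yields no explanatory power
  x$target <- rnorm(150)
  rep0 <- run_regression(x, "target", plan, preprocess = FALSE)
  expect_lte(rep0$summary$r2_mean, 0.05)
})

test_that("odds ratios are exponentiated standardized coefficients", {
  coh <- simulate_classification_cohort(cohort_spec(), seed = 12)
  feats <- c("RMS_VT", "RMS_AP", "HR_AP", "SampEn_AP")
  std <- as.data.frame(scale(coh$features[feats]))
  fit <- fit_model("logistic", std, coh$features$group)
  or <- odds_ratios(fit)
  expect_equal(unname(or), unname(exp(coef(fit$fit)[-1])))
  # direction: higher vertical RMS raises the odds of the stroke-like class
  expect_gt(or[["RMS_VT"]], 1)
  expect_lt(or[["HR_AP"]], 1)
  expect_error(odds_ratios(fit_model("rf", std, coh$features$group)),
               class = "gaitstab_param_error")
})

test_that("partial dependence reproduces linear-model structure", {
  set.seed(4)
  x <- as.data.frame(matrix(rnorm(200 * 3), 200))
  names(x) <- c("a", "b", "c")
  y <- 3 * x$a - 2 * x$b          # c is absent from the model
  fit <- fit_model("linear", x, y)
  pd <- partial_dependence(fit, x, "a", grid = seq(-2, 2, length.out = 20))
  slope <- coef(lm(pd ~ value, pd))[[2]]
  expect_equal(slope, 3, tolerance = 1e-8)
  pd_c <- partial_dependence(fit, x, "c")
  expect_lt(diff(range(pd_c$pd)), 1e-10)
})

test_that("permutation Shapley attributions are exactly additive", {
  set.seed(5)
  reg <- simulate_regression_cohort(cohort_spec(), n = 120, seed = 5)
  pred <- default_reg_predictors()
  rf <- fit_model("rf", reg$features[pred], reg$features$uneven_speed,
                  list(num_trees = 200), seed = 1)
  sh <- shap_values(rf, reg$features[1:15, pred], reg$features[1:60, pred],
                    n_perm = 8, seed = 2)
  expect_lt(max(abs(rowSums(sh$values) - (sh$prediction - sh$base_value))), 1e-3)
  expect_error(shap_values(rf, reg$features[1:5, pred],
                           reg$features[0, pred]),
               class = "gaitstab_param_error")
})

test_that("a single-feature model concentrates all attribution on that feature", {
  set.seed(6)
  x <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  y <- 2 * x$a
  fit <- fit_model("linear", x, y)
  sh <- shap_values(fit, x[1:10, ], x, n_perm = 10, seed = 1)
  share <- colSums(abs(sh$values))
  expect_gt(share[["a"]] / sum(share), 0.999)
})

test_that("exact tree attributions are used for gradient-boosted models", {
  set.seed(7)
  x <- as.data.frame(matrix(rnorm(150 * 4), 150))
  y <- x$V1 + 0.5 * x$V2 + rnorm(150, sd = 0.1)
  gbt <- fit_model("gbt", x, y, list(nrounds = 50, max_depth = 3, eta = 0.2))
  sh <- shap_values(gbt, x[1:10, ], x)
  expect_equal(sh$scale, "margin")
  expect_lt(max(abs(rowSums(sh$values) + sh$base_value - sh$prediction)), 1e-4)
})
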