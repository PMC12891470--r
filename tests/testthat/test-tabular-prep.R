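test_that("IQR outlier replacement uses pre-replacement median and type-7 fences", {
  expect_equal(as.numeric(iqr_impute(c(1, 2, 3, 4, 100))), c(1, 2, 3, 4, 3))
  clean <- c(2, 4, 6, 8, 10)
  expect_equal(as.numeric(iqr_impute(clean)), clean)
  same <- rep(5, 10)
  expect_equal(as.numeric(iqr_impute(same)), same)
  expect_warning(iqr_impute(c(1, 2, 3)), "fewer than 4")
  # train-fitted fences applied to new data
  fit <- iqr_impute(c(1, 2, 3, 4, 5))
  out <- iqr_impute(c(0, 3, 50), params = attr(fit, "params"))
  expect_equal(as.numeric(out), c(0, 3, 3))
})

test_that("Yeo-Johnson transform normalizes skewed columns", {
  skewness <- function(v) mean((v - mean(v))^3) / sd(v)^3
  set.seed(5)
  x <- rexp(500)
  y <- power_transform(x)
  expect_lt(abs(skewness(as.numeric(y))), 0.5)
  expect_true(is.finite(attr(y, "lambda")))
  # already-normal data: transform must not worsen skewness materially
  z <- rnorm(500)
  zt <- power_transform(z)
  expect_lte(abs(skewness(as.numeric(zt))), abs(skewness(z)) + 0.05)
  # lambda = 1 is the identity for non-negative input up to the shift convention
  w <- runif(50)
  expect_equal(as.numeric(power_transform(w, lambda = 1)), w, tolerance = 1e-12)
  expect_warning(power_transform(rep(2, 10)), "constant")
})

test_that("fitted Yeo-Johnson lambda agrees with the car reference", {
  skip_if_not_installed("car")
  set.seed(9)
  x <- rexp(400) + 0.1
  lam_pkg <- attr(power_transform(x), "lambda")
  lam_car <- car::powerTransform(x ~ 1, family = "yjPower")$lambda
  expect_equal(unname(lam_pkg), unname(lam_car), tolerance = 0.02)
})

test_that("z-score standardization stores and reuses train parameters", {
  set.seed(1)
  train <- rnorm(100, 5, 2)
  z <- zscore(train)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  test <- rnorm(50, 7, 2)
  zt <- zscore(test, center = attr(z, "center"), scale = attr(z, "scale"))
  expect_gt(abs(mean(zt)), 0.1)          # test split is not recentred
  expect_error(zscore(rep(1, 10)), class = "gaitstab_param_error")
})

test_that("correlation pruning removes collinear columns deterministically", {
  set.seed(3)
  base <- rnorm(200)
  tab <- data.frame(a = base, b = base + rnorm(200, sd = 1e-6), c = rnorm(200))
  pr <- correlation_prune(tab)
  expect_length(pr$dropped, 1)
  expect_true(pr$dropped %in% c("a", "b"))
  # three mutually collinear columns -> two dropped, final max |r| < 0.9
  tab3 <- data.frame(x = base, y = base + rnorm(200, sd = 0.05),
                     z = -base + rnorm(200, sd = 0.05), w = rnorm(200))
  pr3 <- correlation_prune(tab3)
  expect_length(pr3$dropped, 2)
  cm <- abs(cor(pr3$table))
  diag(cm) <- 0
  expect_lt(max(cm), 0.9)
  # independent noise columns survive in almost all seeds
  kept <- vapply(1:20, function(s) {
    set.seed(s)
    length(correlation_prune(as.data.frame(matrix(rnorm(200 * 6), 200)))$dropped)
  }, numeric(1))
  expect_gte(mean(kept == 0), 0.95)
  expect_error(correlation_prune(data.frame(a = 1:5)),
               class = "gaitstab_param_error")
})

test_that("required sample size reproduces the design power analysis", {
  expect_identical(required_sample_size(0.5, 0.05, 0.8), 64L)
  expect_identical(required_sample_size(1.0, 0.05, 0.8), 17L)
  expect_identical(required_sample_size(0.5, 0.05, 1e-9), 2L)
  # monotonicity: non-increasing in d, non-decreasing in power
  expect_lte(required_sample_size(0.8), required_sample_size(0.5))
  expect_gte(required_sample_size(0.5, power = 0.9),
             required_sample_size(0.5, power = 0.8))
  expect_error(required_sample_size(-1), class = "gaitstab_param_error")
  expect_error(required_sample_size(0.5, alpha = 2), class = "gaitstab_param_error")
})

test_that("the preprocessing chain is fit-on-train / apply-on-test", {
  set.seed(8)
  train <- data.frame(a = rexp(80), b = rnorm(80, 10, 3))
  test <- data.frame(a = rexp(40) + 1, b = rnorm(40, 12, 3))
  fit <- preprocess_fit(train)
  tr <- preprocess_apply(fit, train)
  expect_equal(mean(tr$a), 0, tolerance = 1e-9)
  expect_equal(sd(tr$b), 1, tolerance = 1e-9)
  te <- preprocess_apply(fit, test)
  expect_gt(abs(mean(te$a)), 0.05)       # test stays on train parameters
  # applying the same fitted parameters is deterministic
  expect_identical(te, preprocess_apply(fit, test))
  p <- withr::local_tempfile(fileext = ".json")
  write_preprocess_json(fit, p)
  expect_true(all(c("a", "b") %in% names(jsonlite::read_json(p))))
})
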