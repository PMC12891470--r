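test_that("a perfectly predictive feature is always confirmed", {
  for (s in 1:3) {
    set.seed(s)
    y <- factor(rep(c("A", "B"), each = 40))
    x <- data.frame(hot = as.numeric(y) + rnorm(80, sd = 1e-3),
                    n1 = rnorm(80), n2 = rnorm(80), n3 = rnorm(80))
    b <- boruta_select(x, y, n_iter = 30, seed = s, num_trees = 200)
    expect_true("hot" %in% b$confirmed)
  }
})

test_that("null runs reject almost everything and rarely confirm", {
  # at n = 150 the luckiest of 10 noise features has realized |r| ~ 0.2 and
  # can legitimately beat the shadow bar, so the honest calibration claim is
  # a low average false-confirmation count with mass rejection, not zero
  res <- vapply(1:6, function(s) {
    set.seed(s + 100)
    x <- as.data.frame(matrix(rnorm(150 * 10), 150))
    y <- factor(rep(c("A", "B"), 75))
    b <- boruta_select(x, y, n_iter = 40, seed = s, num_trees = 200)
    c(confirmed = length(b$confirmed), rejected = length(b$rejected))
  }, numeric(2))
  expect_lte(sum(res["confirmed", ]), 6)         # ~0.3 per run measured
  expect_gte(mean(res["rejected", ]), 7)         # the bulk is rejected
})

test_that("an informative feature among noise is separated from the noise", {
  set.seed(42)
  ok <- 0L
  for (s in 1:3) {
    set.seed(s)
    y <- factor(rep(c("A", "B"), each = 60))
    x <- as.data.frame(matrix(rnorm(120 * 10), 120))
    x$V1 <- x$V1 + 1.5 * (as.numeric(y) - 1)      # d = 1.5
    b <- boruta_select(x, y, n_iter = 60, seed = s, num_trees = 300)
    ok <- ok + ("V1" %in% b$confirmed && length(b$rejected) >= 8)
  }
  expect_gte(ok, 2)
})

test_that("boruta warns on too few iterations", {
  set.seed(1)
  x <- data.frame(a = rnorm(50), b = rnorm(50))
  expect_warning(boruta_select(x, rnorm(50), n_iter = 10, num_trees = 100),
                 "unstable")
})

test_that("lasso selection finds predictive features and respects shrinkage", {
  set.seed(2)
  n <- 100
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(ifelse(x[, 1] + rnorm(n, sd = 0.3) > 0, "B", "A"))
  ls <- lasso_select(x, y, seed = 3)
  expect_true("f1" %in% ls$selected)
  # the largest lambda of the path shrinks everything to zero
  path <- ls$cvfit$glmnet.fit
  expect_equal(sum(abs(path$beta[, 1])), 0)
  expect_true(is.finite(ls$log_lambda))
  # column-order invariance
  ls_rev <- lasso_select(x[, 6:1], y, seed = 3)
  expect_setequal(ls$selected, ls_rev$selected)
})

test_that("the lasso path matches the soft-threshold closed form on orthonormal designs", {
  set.seed(1)
  n <- 64; p <- 8
  x <- qr.Q(qr(matrix(rnorm(n * p), n))) * sqrt(n)   # t(x) %*% x = n I
  colnames(x) <- paste0("f", 1:p)
  beta <- c(2, -1.5, 1, 0.5, rep(0, 4))
  y <- drop(x %*% beta)
  ls <- lasso_select(x, y, seed = 1, standardize = FALSE, intercept = FALSE,
                     thresh = 1e-14)
  path <- ls$cvfit$glmnet.fit
  ols <- drop(crossprod(x, y)) / n
  closed <- sapply(path$lambda, function(l) sign(ols) * pmax(abs(ols) - l, 0))
  expect_lt(max(abs(as.matrix(path$beta) - closed)), 1e-6)
})

test_that("consensus is the exact intersection with an empty-set flag", {
  expect_setequal(consensus_features(c("a", "b"), c("b", "a")), c("a", "b"))
  expect_warning(out <- consensus_features(c("a"), c("b")), "empty")
  expect_length(out, 0)
  expect_true(attr(out, "empty"))
  # works directly on result objects
  b <- structure(list(confirmed = c("x", "y")), class = "boruta_result")
  l <- structure(list(selected = c("y", "z")), class = "lasso_result")
  expect_equal(consensus_features(b, l), "y")
})

test_that("selection report serializes to JSON", {
  set.seed(4)
  x <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  y <- factor(rep(c("A", "B"), 30))
  b <- suppressWarnings(boruta_select(x, y, n_iter = 20, num_trees = 100))
  l <- lasso_select(x, y, seed = 1)
  cons <- suppressWarnings(consensus_features(b, l))
  p <- withr::local_tempfile(fileext = ".json")
  write_selection_json(b, l, cons, p)
  rep <- jsonlite::read_json(p)
  expect_named(rep, c("boruta", "lasso", "consensus"))
  expect_equal(rep$boruta$n_iter, 20)
})
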