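# Uniform wrappers over the classification / regression learners so the
# experiment harness, grids, PDP and Shapley code can treat every model as
# fit(x, y, params) + predict(x) -> probability or numeric prediction.

clf_kinds <- function() c("logistic", "dt", "svc", "gbt", "rf", "knn")
reg_kinds <- function() c("linear", "svr", "enet", "rf", "gbt", "knn")

#' Default hyperparameter grids
#'
#' One list of parameter combinations per model family. Glass-box models have
#' small or empty grids; the kernel / tree families cover the conventional
#' cost, depth and neighbourhood ranges.
#'
#' @param task `"classification"` or `"regression"`.
#' @return Named list: per model kind, a list of parameter lists.
#' @export
default_grids <- function(task = c("classification", "regression")) {
  task <- match.arg(task)
  expand_grid_list <- function(...) {
    g <- expand.grid(..., stringsAsFactors = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
  }
  shared <- list(
    rf = expand_grid_list(num_trees = c(200, 500), max_depth = c(0, 5, 10)),
    gbt = expand_grid_list(nrounds = 100, max_depth = c(3, 6), eta = c(0.1, 0.3)),
    knn = expand_grid_list(k = c(3, 5, 7, 9)))
  if (task == "classification") {
    c(list(logistic = list(list()),
           dt = expand_grid_list(cp = c(0.01, 0.001), maxdepth = c(5, 10)),
           svc = expand_grid_list(cost = c(0.1, 1, 10), gamma_rule = c("scale", "fixed"))),
      shared)
  } else {
    c(list(linear = list(list()),
           svr = expand_grid_list(cost = c(0.1, 1, 10), gamma_rule = c("scale", "fixed")),
           enet = expand_grid_list(alpha = c(0.2, 0.5, 0.8),
                                   lambda = 10^seq(-3, 0, length.out = 4))),
      shared)
  }
}

svm_gamma <- function(rule, x) if (identical(rule, "fixed")) 0.01 else 1 / ncol(x)

#' Fit one model of the suite
#'
#' @param kind Model family: one of `logistic, dt, svc, gbt, rf, knn`
#'   (classification) or `linear, svr, enet, rf, gbt, knn` (regression).
#' @param x Data.frame/matrix of numeric features.
#' @param y Factor (2 levels, second = positive class) or numeric response.
#' @param params Named list of hyperparameters (see [default_grids()]).
#' @param seed Integer seed for the stochastic learners.
#' @return Object of class `gs_model`; predictions via [predict.gs_model()].
#' @export
fit_model <- function(kind, x, y, params = list(), seed = 1L) {
  x <- as.data.frame(x)
  task <- if (is.factor(y)) "classification" else "regression"
  xm <- as.matrix(x)
  fit <- with_seed(seed, switch(
    paste(task, kind, sep = "."),
    classification.logistic = {
      d <- x; d$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
    },
    classification.dt = {
      d <- x; d$.y <- y
      rpart::rpart(.y ~ ., data = d, method = "class",
                   control = rpart::rpart.control(
                     cp = params$cp %||% 0.01,
                     maxdepth = params$maxdepth %||% 30L, xval = 0L))
    },
    classification.svc = e1071::svm(
      xm, y, kernel = "radial", cost = params$cost %||% 1,
      gamma = svm_gamma(params$gamma_rule, x), probability = TRUE, scale = FALSE),
    classification.gbt = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 6L,
                    eta = params$eta %||% 0.3, nthread = 1L),
      data = xgboost::xgb.DMatrix(xm, label = as.numeric(y) - 1),
      nrounds = params$nrounds %||% 100L, verbose = 0L),
    classification.rf = {
      d <- x; d$.y <- y
      ranger::ranger(.y ~ ., data = d, probability = TRUE,
                     num.trees = params$num_trees %||% 500L,
                     max.depth = params$max_depth %||% 0L,
                     num.threads = 1L, seed = seed, verbose = FALSE)
    },
    classification.knn = caret::knn3(xm, y, k = params$k %||% 5L),
    regression.linear = {
      d <- x; d$.y <- y
      stats::lm(.y ~ ., data = d)
    },
    regression.svr = e1071::svm(
      xm, y, kernel = "radial", cost = params$cost %||% 1,
      gamma = svm_gamma(params$gamma_rule, x), scale = FALSE),
    regression.enet = glmnet::glmnet(
      xm, y, alpha = params$alpha %||% 0.5, lambda = params$lambda %||% 0.01),
    regression.rf = {
      d <- x; d$.y <- y
      ranger::ranger(.y ~ ., data = d,
                     num.trees = params$num_trees %||% 500L,
                     max.depth = params$max_depth %||% 0L,
                     num.threads = 1L, seed = seed, verbose = FALSE)
    },
    regression.gbt = xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = params$max_depth %||% 6L,
                    eta = params$eta %||% 0.3, nthread = 1L),
      data = xgboost::xgb.DMatrix(xm, label = y),
      nrounds = params$nrounds %||% 100L, verbose = 0L),
    regression.knn = caret::knnreg(xm, y, k = params$k %||% 5L),
    gs_param_error(sprintf("unknown model kind '%s' for %s", kind, task))
  ))
  structure(list(kind = kind, task = task, fit = fit, params = params,
                 feature_names = colnames(x),
                 positive = if (task == "classification") levels(y)[2L] else NULL,
                 levels = if (task == "classification") levels(y) else NULL),
            class = "gs_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict from a fitted suite model
#'
#' @param object A `gs_model`.
#' @param newdata Data.frame/matrix with the training feature columns.
#' @param ... Unused.
#' @return For classification, the probability of the positive (second-level)
#'   class; for regression, the numeric prediction.
#' @export
predict.gs_model <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)[object$feature_names]
  xm <- as.matrix(x)
  if (object$task == "classification") {
    pos <- object$positive
    switch(object$kind,
      logistic = as.numeric(stats::predict(object$fit, x, type = "response")),
      dt = stats::predict(object$fit, x, type = "prob")[, pos],
      svc = {
        pr <- stats::predict(object$fit, xm, probability = TRUE)
        attr(pr, "probabilities")[, pos]
      },
      gbt = as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(xm))),
      rf = stats::predict(object$fit, data = x)$predictions[, pos],
      knn = stats::predict(object$fit, xm, type = "prob")[, pos])
  } else {
    switch(object$kind,
      linear = as.numeric(stats::predict(object$fit, x)),
      svr = as.numeric(stats::predict(object$fit, xm)),
      enet = as.numeric(stats::predict(object$fit, xm))[seq_len(nrow(xm))],
      rf = stats::predict(object$fit, data = x)$predictions,
      gbt = as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(xm))),
      knn = as.numeric(stats::predict(object$fit, xm)))
  }
}

#' @export
print.gs_model <- function(x, ...) {
  cat(sprintf("<gs_model> %s (%s)\n", x$kind, x$task))
  invisible(x)
}

# ---- evaluation metrics ----------------------------------------------------

#' Classification and regression evaluation metrics
#'
#' `roc_auc` is the rank-sum (Mann-Whitney) statistic, handling ties by
#' midranks; `brier_score` the mean squared probability error;
#' `classification_metrics` adds sensitivity, specificity and F1 at the 0.5
#' threshold. `regression_metrics` returns R^2, RMSE, MAE and MSE.
#'
#' @param scores Numeric scores or probabilities for the positive class.
#' @param labels Binary labels: factor (second level = positive) or 0/1.
#' @param probs Probabilities in `[0, 1]`.
#' @param truth,pred Numeric vectors for regression.
#' @param threshold Decision threshold (default 0.5).
#' @return `roc_auc`, `brier_score`: a scalar; the `*_metrics` functions a
#'   named numeric vector.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))  # 1
#' @name eval_metrics
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.factor(labels)) labels == levels(labels)[2L] else labels > 0
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) gs_param_error("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname eval_metrics
#' @export
brier_score <- function(probs, labels) {
  y <- if (is.factor(labels)) as.numeric(labels == levels(labels)[2L]) else as.numeric(labels > 0)
  mean((probs - y)^2)
}

#' @rdname eval_metrics
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  y <- if (is.factor(labels)) labels == levels(labels)[2L] else labels > 0
  pred <- scores >= threshold
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (isTRUE(prec + sens > 0)) 2 * prec * sens / (prec + sens) else 0
  c(auc = roc_auc(scores, labels), sensitivity = sens, specificity = spec,
    f1 = f1, brier = brier_score(scores, labels))
}

#' @rdname eval_metrics
#' @export
regression_metrics <- function(truth, pred) {
  mse <- mean((truth - pred)^2)
  c(r2 = 1 - mse / mean((truth - mean(truth))^2),
    rmse = sqrt(mse), mae = mean(abs(truth - pred)), mse = mse)
}
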