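# Model interpretation: odds ratios, partial dependence, Shapley
# attributions, and locators that read embedded nonlinear structure
# (breakpoints, plateaus, U-shapes) back off interpretation curves.

#' Odds ratios of a fitted logistic model
#'
#' `exp(coefficient)` per feature; with standardized inputs each value is the
#' multiplicative change in the odds of the positive class per SD.
#'
#' @param model A `gs_model` of kind `"logistic"`, or a `glm` fit.
#' @return Named numeric vector of odds ratios (intercept excluded).
#' @export
odds_ratios <- function(model) {
  fit <- if (inherits(model, "gs_model")) model$fit else model
  if (!inherits(fit, "glm")) gs_param_error("odds ratios require a logistic model")
  co <- stats::coef(fit)
  exp(co[names(co) != "(Intercept)"])
}

#' Partial dependence of a model on one feature
#'
#' For each grid value `g`, the mean model prediction over the data with the
#' feature column replaced by `g` (all other columns untouched).
#'
#' @param model A `gs_model` (or any object with a `predict` method taking a
#'   data.frame).
#' @param x Data.frame of feature rows to average over.
#' @param feature Feature name.
#' @param grid Numeric grid (default: 40 quantile-spanned points).
#' @return Data.frame with columns `value` and `pd`.
#' @export
partial_dependence <- function(model, x, feature, grid = NULL) {
  x <- as.data.frame(x)
  if (!feature %in% names(x)) gs_param_error("feature not in data")
  if (is.null(grid))
    grid <- seq(stats::quantile(x[[feature]], 0.02),
                stats::quantile(x[[feature]], 0.98), length.out = 40L)
  pd <- vapply(grid, function(g) {
    xg <- x
    xg[[feature]] <- g
    mean(predict(model, xg))
  }, numeric(1))
  data.frame(value = grid, pd = pd)
}

#' Permutation-sampling Shapley attributions
#'
#' Model-agnostic Shapley values by Monte-Carlo over feature orderings: for
#' each sampled permutation the features of the explained row are switched in
#' one at a time over the background rows, and each feature is credited with
#' the change in mean prediction. Because the per-permutation contributions
#' telescope, the attributions sum *exactly* to
#' `f(x) - mean(f(background))` for every sample (the additivity axiom).
#' For xgboost models the exact tree-path attributions
#' (`predict(..., predcontrib = TRUE)`) are used instead.
#'
#' @param model A `gs_model`.
#' @param x_explain Rows to explain (data.frame).
#' @param x_background Background rows defining the expectation (non-empty).
#' @param n_perm Permutations per explained row (default 20).
#' @param seed Integer seed.
#' @param exact_tree Use exact tree attributions for xgboost models
#'   (default TRUE).
#' @return List of class `shap_result`: `values` (matrix rows x features),
#'   `base_value` (mean background prediction), `prediction` (per row),
#'   `importance` (global mean absolute attribution, sorted).
#' @export
shap_values <- function(model, x_explain, x_background, n_perm = 20L,
                        seed = 1L, exact_tree = TRUE) {
  x_explain <- as.data.frame(x_explain)[model$feature_names]
  x_background <- as.data.frame(x_background)[model$feature_names]
  if (nrow(x_background) == 0L) gs_param_error("background set is empty")
  p <- length(model$feature_names)
  if (exact_tree && model$kind == "gbt" && inherits(model$fit, "xgb.Booster")) {
    contrib <- stats::predict(model$fit, xgboost::xgb.DMatrix(as.matrix(x_explain)),
                              predcontrib = TRUE)
    vals <- contrib[, seq_len(p), drop = FALSE]
    colnames(vals) <- model$feature_names
    base <- contrib[1L, p + 1L]
    pred_margin <- rowSums(contrib)
    res <- list(values = vals, base_value = base, prediction = pred_margin,
                scale = "margin")
  } else {
    nb <- nrow(x_background)
    base <- mean(predict(model, x_background))
    vals <- matrix(0, nrow(x_explain), p,
                   dimnames = list(NULL, model$feature_names))
    preds <- numeric(nrow(x_explain))
    with_seed(seed, {
      for (i in seq_len(nrow(x_explain))) {
        xi <- x_explain[i, , drop = FALSE]
        acc <- numeric(p)
        for (s in seq_len(n_perm)) {
          ord <- sample.int(p)
          cur <- x_background
          prev_mean <- base
          for (j in ord) {
            cur[[j]] <- xi[[j]]
            new_mean <- mean(predict(model, cur))
            acc[j] <- acc[j] + (new_mean - prev_mean)
            prev_mean <- new_mean
          }
        }
        vals[i, ] <- acc / n_perm
        preds[i] <- predict(model, xi)
      }
    })
    # telescoping makes rowSums(vals) = f(x) - base up to the Monte-Carlo
    # average, which is exact because every permutation telescopes fully
    res <- list(values = vals, base_value = base, prediction = preds,
                scale = "response")
  }
  res$importance <- sort(colMeans(abs(res$values)), decreasing = TRUE)
  structure(res, class = "shap_result")
}

#' @export
print.shap_result <- function(x, ...) {
  cat(sprintf("<shap_result> %d samples x %d features (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("top features:", paste(utils::head(names(x$importance), 5), collapse = ", "), "\n")
  invisible(x)
}

#' Global Shapley summary for a model
#'
#' Convenience wrapper around [shap_values()] returning per-feature global
#' importance (mean absolute attribution) alongside the raw values.
#'
#' @inheritParams shap_values
#' @return A `shap_result` (see [shap_values()]).
#' @export
shap_summary <- function(model, x_background, x_explain, n_perm = 20L, seed = 1L) {
  shap_values(model, x_explain, x_background, n_perm = n_perm, seed = seed)
}

#' Locate a breakpoint in a curve by two-segment least squares
#'
#' Grid search over candidate breakpoints: each candidate fits a continuous
#' two-segment linear model and the candidate with minimal residual sum of
#' squares is returned. Used to read a changepoint (e.g. the 0.8 m/s speed
#' breakpoint) off a partial-dependence curve or raw scatter.
#'
#' @param x,y Numeric vectors.
#' @param candidates Candidate breakpoints (default: interior 10-90 %
#'   quantile grid of 81 points).
#' @return The breakpoint estimate (scalar), with attribute `sse`.
#' @export
locate_breakpoint <- function(x, y, candidates = NULL) {
  if (is.null(candidates))
    candidates <- seq(stats::quantile(x, 0.1), stats::quantile(x, 0.9),
                      length.out = 81L)
  sse <- vapply(candidates, function(c0) {
    h <- pmax(x - c0, 0)
    f <- stats::lm(y ~ x + h)
    sum(stats::resid(f)^2)
  }, numeric(1))
  structure(candidates[which.min(sse)], sse = min(sse))
}

#' Locate a breakpoint on a random-forest partial-dependence curve
#'
#' Changepoint locator for slope breaks read off forest PDP curves. Tree
#' ensembles concentrate their split points where the target's slope changes,
#' so the partial-dependence curve of a kinked relationship shows its sharpest
#' local rise — the point of maximal discrete curvature change — at the
#' embedded breakpoint, while global spline curvature is dominated by the
#' attenuation of the curve near the data edges. The locator therefore
#' averages the PDP over `n_forests` independently seeded forests, takes
#' first differences on an equally spaced grid, lightly smooths them
#' (3-point mean), and returns the grid midpoint of the steepest rise.
#'
#' @param data Data.frame with predictors and target.
#' @param target Target column name.
#' @param feature Feature along which to locate the breakpoint.
#' @param predictors Predictor columns (default: all numeric except target).
#' @param n_forests Forests averaged per PDP (default 8).
#' @param num_trees Trees per forest (default 700).
#' @param grid_size PDP grid points between the 5th and 95th feature
#'   percentile (default 43).
#' @param seed Integer seed.
#' @return Breakpoint estimate (scalar) with attribute `pd` holding the
#'   averaged curve.
#' @export
pdp_locate_breakpoint <- function(data, target, feature, predictors = NULL,
                                  n_forests = 8L, num_trees = 700L,
                                  grid_size = 43L, seed = 1L) {
  data <- as.data.frame(data)
  if (is.null(predictors))
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          target)
  dtr <- data[predictors]
  dtr$.y <- data[[target]]
  g <- seq(stats::quantile(data[[feature]], 0.05),
           stats::quantile(data[[feature]], 0.95), length.out = grid_size)
  pdv <- 0
  for (rs in seq_len(n_forests)) {
    fit <- ranger::ranger(.y ~ ., data = dtr, num.trees = num_trees,
                          min.node.size = 3L, num.threads = 1L,
                          seed = seed + rs, verbose = FALSE)
    pdv <- pdv + vapply(g, function(v) {
      dd <- data[predictors]
      dd[[feature]] <- v
      mean(stats::predict(fit, data = dd)$predictions)
    }, numeric(1)) / n_forests
  }
  d1 <- diff(pdv) / diff(g)
  d1s <- as.numeric(stats::filter(d1, rep(1 / 3, 3)))
  mid <- (g[-1L] + g[-length(g)]) / 2
  structure(mid[which.max(d1s)], pd = data.frame(value = g, pd = pdv))
}

#' Locate a ramp-plateau knee in a curve
#'
#' Fits `y ~ pmin(x, c)` over a candidate grid and returns the saturation
#' point `c` with minimal residual sum of squares (e.g. the even-surface
#' harmonic-ratio value beyond which the uneven-surface ratio stops rising).
#'
#' @inheritParams locate_breakpoint
#' @return The plateau-onset estimate, with attribute `sse`.
#' @export
locate_plateau <- function(x, y, candidates = NULL) {
  if (is.null(candidates))
    candidates <- seq(stats::quantile(x, 0.1), stats::quantile(x, 0.9),
                      length.out = 81L)
  sse <- vapply(candidates, function(c0) {
    f <- stats::lm(y ~ pmin(x, c0))
    sum(stats::resid(f)^2)
  }, numeric(1))
  structure(candidates[which.min(sse)], sse = min(sse))
}

#' Quadratic (U-shape) fit of a curve
#'
#' Least-squares quadratic `y = a + b x + c x^2`; a positive `c` with vertex
#' inside the data range indicates a U-shaped dependency.
#'
#' @param x,y Numeric vectors.
#' @return List: `quad_coef` (c), `vertex` (-b / 2c), `coefficients`.
#' @export
fit_ushape <- function(x, y) {
  f <- stats::lm(y ~ x + I(x^2))
  co <- stats::coef(f)
  list(quad_coef = unname(co[3L]),
       vertex = unname(-co[2L] / (2 * co[3L])),
       coefficients = co)
}

#' Export interpretation artifacts as CSV
#'
#' @param pd A partial-dependence data.frame from [partial_dependence()].
#' @param shap A `shap_result`.
#' @param pd_path,shap_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_interpretation_csv <- function(pd = NULL, shap = NULL,
                                     pd_path = NULL, shap_path = NULL) {
  if (!is.null(pd) && !is.null(pd_path))
    utils::write.csv(pd, pd_path, row.names = FALSE)
  if (!is.null(shap) && !is.null(shap_path))
    utils::write.csv(as.data.frame(shap$values), shap_path, row.names = FALSE)
  invisible(c(pd_path, shap_path))
}
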