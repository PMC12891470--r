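# Consensus feature selection: a shadow-feature random-forest wrapper
# (Boruta-style) intersected with an L1-penalized path.

#' Boruta-style shadow-feature selection
#'
#' Sequential shadow-feature wrapper. Each iteration appends a permuted
#' ("shadow") copy of every original feature, fits a random-forest
#' permutation-importance model (ranger, 500 trees, sqrt-features split),
#' and scores a *hit* for every undecided feature whose importance exceeds
#' the maximum shadow importance. From `burn_in` iterations on, each
#' undecided feature is tested against Binomial(active iterations, 0.5)
#' two-sidedly with Bonferroni correction over the feature count:
#' significantly more hits than chance confirms, significantly fewer
#' rejects — and rejected features leave the model (reducing importance
#' dilution, which is what gives the sequential procedure its power), while
#' the shadow pool always contains all original features so the null
#' reference never weakens. Features unresolved after `n_iter` are
#' tentative.
#'
#' @param x Data.frame or matrix of features.
#' @param y Response: factor/binary (classification) or numeric (regression).
#' @param n_iter Maximum number of shadow iterations (default 100; < 20
#'   warns).
#' @param alpha Significance level for the binomial decision (default 0.05).
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 500).
#' @param burn_in Iterations before the first decision (default 10).
#' @return List of class `boruta_result`: `confirmed`, `tentative`,
#'   `rejected` (character vectors), `hits` and `n_active` (per-feature
#'   counts), `n_iter`.
#' @export
boruta_select <- function(x, y, n_iter = 100L, alpha = 0.05, seed = 1L,
                          num_trees = 500L, burn_in = 10L) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) gs_param_error("need at least 2 features")
  if (n_iter < 20L) warning("n_iter < 20 gives unstable Boruta decisions")
  if (is.character(y) || is.logical(y)) y <- factor(y)
  p <- ncol(x)
  feat <- names(x)
  hits <- setNames(integer(p), feat)
  n_active <- setNames(integer(p), feat)
  status <- setNames(rep("undecided", p), feat)
  thr <- alpha / p
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      undecided <- feat[status == "undecided"]
      if (length(undecided) == 0L) break
      active <- feat[status %in% c("undecided", "confirmed")]
      # shadows are permuted copies of *all* original features: the shadow
      # ensemble is the null reference distribution and must not shrink as
      # features are rejected, or surviving noise features would face an
      # ever-lower bar and win on realized in-sample correlation alone
      shadow <- as.data.frame(lapply(x, sample))
      names(shadow) <- paste0("shadow_", seq_len(p))
      dat <- cbind(x[active], shadow)
      dat$.y <- y
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = dat,
        num.trees = num_trees, mtry = max(1L, floor(sqrt(ncol(dat) - 1L))),
        importance = "permutation", num.threads = 1L,
        seed = sample.int(.Machine$integer.max, 1L), verbose = FALSE)
      imp <- fit$variable.importance
      max_shadow <- max(imp[paste0("shadow_", seq_len(p))])
      hits[undecided] <- hits[undecided] + (imp[undecided] > max_shadow)
      n_active[undecided] <- n_active[undecided] + 1L
      if (it >= burn_in) {
        for (f in undecided) {
          p_hi <- stats::pbinom(hits[[f]] - 1L, n_active[[f]], 0.5,
                                lower.tail = FALSE)
          p_lo <- stats::pbinom(hits[[f]], n_active[[f]], 0.5)
          if (p_hi < thr) status[[f]] <- "confirmed"
          else if (p_lo < thr) status[[f]] <- "rejected"
        }
      }
    }
  })
  structure(list(confirmed = feat[status == "confirmed"],
                 tentative = feat[status == "undecided"],
                 rejected = feat[status == "rejected"],
                 hits = hits, n_active = n_active, n_iter = n_iter,
                 alpha = alpha),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("<boruta_result> %d confirmed, %d tentative, %d rejected (%d iterations)\n",
              length(x$confirmed), length(x$tentative), length(x$rejected), x$n_iter))
  invisible(x)
}

#' LASSO feature selection along a cross-validated path
#'
#' L1-penalized logistic (binary `y`) or linear (numeric `y`) regression via
#' glmnet; lambda chosen by cross-validated deviance/MSE under `lambda_min`
#' (default) or `lambda_1se`. Selected features are those with nonzero
#' coefficients at the chosen lambda.
#'
#' @param x Matrix or data.frame of standardized features.
#' @param y Binary factor or numeric response.
#' @param n_folds CV folds (default 5).
#' @param rule `"lambda_min"` or `"lambda_1se"`.
#' @param seed Integer seed (controls fold assignment).
#' @param ... Further arguments passed to [glmnet::cv.glmnet()] (e.g.
#'   `standardize`, `intercept`, `lambda`, `thresh`).
#' @return List of class `lasso_result`: `selected` (character),
#'   `lambda` (chosen value), `log_lambda`, `coefficients` at the chosen
#'   lambda, and the full `cvfit` object (its `$glmnet.fit` holds the path).
#' @export
lasso_select <- function(x, y, n_folds = 5L, rule = c("lambda_min", "lambda_1se"),
                         seed = 1L, ...) {
  rule <- match.arg(rule)
  xm <- as.matrix(as.data.frame(x)[vapply(as.data.frame(x), is.numeric, logical(1))])
  if (is.character(y)) y <- factor(y)
  fam <- if (is.factor(y) || all(y %in% 0:1)) "binomial" else "gaussian"
  cvfit <- with_seed(seed,
    glmnet::cv.glmnet(xm, y, family = fam, nfolds = n_folds, ...))
  lam <- if (rule == "lambda_min") cvfit$lambda.min else cvfit$lambda.1se
  co <- as.matrix(stats::coef(cvfit, s = lam))
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  selected <- rownames(co)[abs(co[, 1L]) > 0]
  structure(list(selected = selected, lambda = lam, log_lambda = log(lam),
                 coefficients = co[, 1L], cvfit = cvfit, rule = rule),
            class = "lasso_result")
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf("<lasso_result> %d features at log(lambda) = %.3f (%s)\n",
              length(x$selected), x$log_lambda, x$rule))
  invisible(x)
}

#' Consensus of two feature-selection results
#'
#' The exact intersection of the two selected sets; features chosen by both
#' methods are deemed robust. Boruta tentative features are *not* counted as
#' selected. An empty intersection is allowed but flagged with a warning.
#'
#' @param a,b Character vectors of selected feature names, or
#'   `boruta_result` / `lasso_result` objects.
#' @return Character vector of consensus features, with attribute
#'   `empty = TRUE` when the intersection is empty.
#' @export
consensus_features <- function(a, b) {
  as_set <- function(z) {
    if (inherits(z, "boruta_result")) return(z$confirmed)
    if (inherits(z, "lasso_result")) return(z$selected)
    as.character(z)
  }
  out <- intersect(as_set(a), as_set(b))
  if (length(out) == 0L) {
    warning("consensus feature set is empty")
    return(structure(character(0), empty = TRUE))
  }
  out
}

#' Write a feature-selection report as JSON
#'
#' @param boruta A `boruta_result`.
#' @param lasso A `lasso_result`.
#' @param consensus Character vector from [consensus_features()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_selection_json <- function(boruta, lasso, consensus, path) {
  rep <- list(
    boruta = list(confirmed = boruta$confirmed, tentative = boruta$tentative,
                  rejected = boruta$rejected, hits = as.list(boruta$hits),
                  n_iter = boruta$n_iter),
    lasso = list(selected = lasso$selected, log_lambda = lasso$log_lambda,
                 rule = lasso$rule,
                 coefficients = as.list(lasso$coefficients)),
    consensus = as.character(consensus))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
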