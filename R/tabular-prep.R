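# Feature-table normalization: outlier replacement, power transform, z-score,
# correlation pruning, and the design-stage power computation. Every transform
# is fit on the training split and applied with the stored parameters to test
# data, so no test row can influence the preprocessing.

#' Replace IQR outliers with the median
#'
#' Values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (quartiles by linear
#' interpolation, type 7) are replaced with the pre-replacement median. When
#' `params` is supplied (fitted on a training split) its fences and median are
#' reused instead of refitting.
#'
#' @param x Numeric vector (at least 4 observations to fit).
#' @param params Optional list `(lower, upper, center)` from a previous fit.
#' @return The imputed vector, with the fitted parameters attached as
#'   attribute `params`.
#' @examples
#' iqr_impute(c(1, 2, 3, 4, 100))  # -> 1 2 3 4 3
#' @export
iqr_impute <- function(x, params = NULL) {
  if (is.null(params)) {
    if (sum(is.finite(x)) < 4L) {
      warning("fewer than 4 observations; returning column unchanged")
      return(structure(x, params = list(lower = -Inf, upper = Inf,
                                        center = median(x, na.rm = TRUE))))
    }
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
    iqr <- q[2L] - q[1L]
    params <- list(lower = q[1L] - 1.5 * iqr, upper = q[2L] + 1.5 * iqr,
                   center = median(x, na.rm = TRUE))
  }
  out <- ifelse(x < params$lower | x > params$upper, params$center, x)
  structure(out, params = params)
}

# Yeo-Johnson transform for a fixed lambda
yeo_johnson <- function(x, lambda) {
  pos <- x >= 0
  y <- numeric(length(x))
  if (abs(lambda) > 1e-10) {
    y[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    y[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    y[!pos] <- -((-x[!pos] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    y[!pos] <- -log1p(-x[!pos])
  }
  y
}

#' Yeo-Johnson power transform with maximum-likelihood lambda
#'
#' Normalizes a skewed feature column. When `lambda` is `NULL` it is fitted by
#' maximizing the Gaussian profile log-likelihood over `[-5, 5]`; pass a fitted
#' `lambda` to transform test data with the training value.
#'
#' @param x Numeric vector with finite values.
#' @param lambda Optional fixed transform parameter.
#' @return Transformed vector with the (fitted or supplied) `lambda` as an
#'   attribute.
#' @export
power_transform <- function(x, lambda = NULL) {
  if (!all(is.finite(x))) gs_param_error("power_transform requires finite values")
  if (length(unique(x)) == 1L) {
    warning("constant column; power transform skipped")
    return(structure(x, lambda = 1))
  }
  if (is.null(lambda)) {
    n <- length(x)
    ll <- function(lam) {
      y <- yeo_johnson(x, lam)
      -n / 2 * log(mean((y - mean(y))^2)) +
        (lam - 1) * sum(sign(x) * log1p(abs(x)))
    }
    lambda <- stats::optimize(ll, c(-5, 5), maximum = TRUE)$maximum
  }
  structure(yeo_johnson(x, lambda), lambda = lambda)
}

#' Z-score standardization with reusable parameters
#'
#' @param x Numeric vector.
#' @param center,scale Optional training-split mean and SD; fitted from `x`
#'   when `NULL`.
#' @return Standardized vector with attributes `center` and `scale`.
#' @export
zscore <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- mean(x)
  if (is.null(scale)) scale <- stats::sd(x)
  if (!is.finite(scale) || scale == 0)
    gs_param_error("cannot z-score a constant column")
  structure((x - center) / scale, center = center, scale = scale)
}

#' Greedy correlation pruning
#'
#' While any pair of columns has `|Pearson r| >= threshold`, the member of the
#' worst pair with the larger mean absolute correlation to all other columns
#' is dropped (ties broken towards the later column), giving a deterministic
#' reduced set with maximal pairwise correlation below the threshold.
#'
#' @param table Data.frame or matrix of numeric feature columns (>= 2).
#' @param threshold Correlation threshold (default 0.9).
#' @return List with `table` (reduced columns) and `dropped` (character).
#' @export
correlation_prune <- function(table, threshold = 0.9) {
  x <- as.data.frame(table)
  num <- vapply(x, is.numeric, logical(1))
  if (sum(num) < 2L) gs_param_error("need at least 2 numeric columns")
  keep <- names(x)[num]
  dropped <- character(0)
  repeat {
    cm <- abs(stats::cor(x[keep]))
    diag(cm) <- 0
    if (max(cm) < threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    mean_abs <- colMeans(abs(cm))
    pair <- keep[worst]
    drop <- if (mean_abs[worst[1L]] > mean_abs[worst[2L]]) pair[1L] else pair[2L]
    dropped <- c(dropped, drop)
    keep <- setdiff(keep, drop)
    if (length(keep) < 2L) break
  }
  list(table = x[c(names(x)[!num], keep)], dropped = dropped)
}

#' Required sample size for a two-sample t comparison
#'
#' Smallest per-group n giving at least the target power for a two-sided
#' two-sample t test at standardized effect size `d` (noncentral-t power via
#' [stats::power.t.test()], equal group sizes).
#'
#' @param effect_size_d Standardized mean difference (> 0).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Integer n per group (minimum 2).
#' @examples
#' required_sample_size(0.5, 0.05, 0.8)  # 64
#' @export
required_sample_size <- function(effect_size_d, alpha = 0.05, power = 0.8) {
  if (!is_scalar_num(effect_size_d) || effect_size_d <= 0)
    gs_param_error("effect size must be positive")
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 1)
    gs_param_error("alpha must be in (0, 1)")
  if (!is_scalar_num(power) || power <= 0 || power >= 1)
    gs_param_error("power must be in (0, 1)")
  n <- 2L
  repeat {
    p <- stats::power.t.test(n = n, delta = effect_size_d, sd = 1,
                             sig.level = alpha)$power
    if (p >= power) return(n)
    n <- n + 1L
    if (n > 1e6) gs_param_error("required sample size exceeds 1e6")
  }
}

#' Fit / apply the full preprocessing chain on a feature table
#'
#' Applies, per numeric column and in order: IQR outlier replacement,
#' Yeo-Johnson power transform, z-score standardization. `preprocess_fit`
#' learns all parameters from the training split; `preprocess_apply` applies
#' them unchanged to new rows, so test data never influence the transform.
#'
#' @param table Data.frame with numeric feature columns.
#' @param cols Character vector of columns to transform (default: all numeric).
#' @param fitted A fit from `preprocess_fit`.
#' @return `preprocess_fit`: list of class `preprocess_fit` with per-column
#'   parameters; `preprocess_apply`: the transformed data.frame.
#' @name preprocess
#' @export
preprocess_fit <- function(table, cols = NULL) {
  if (is.null(cols)) cols <- names(table)[vapply(table, is.numeric, logical(1))]
  params <- lapply(cols, function(cn) {
    v1 <- iqr_impute(table[[cn]])
    v2 <- power_transform(as.numeric(v1))
    v3 <- zscore(as.numeric(v2))
    list(iqr = attr(v1, "params"), lambda = attr(v2, "lambda"),
         center = attr(v3, "center"), scale = attr(v3, "scale"))
  })
  names(params) <- cols
  structure(list(cols = cols, params = params), class = "preprocess_fit")
}

#' @rdname preprocess
#' @export
preprocess_apply <- function(fitted, table) {
  stopifnot(inherits(fitted, "preprocess_fit"))
  out <- table
  for (cn in fitted$cols) {
    p <- fitted$params[[cn]]
    v <- as.numeric(iqr_impute(table[[cn]], params = p$iqr))
    v <- yeo_johnson(v, p$lambda)
    out[[cn]] <- (v - p$center) / p$scale
  }
  out
}

#' Serialize fitted preprocessing parameters to JSON
#' @param fitted A `preprocess_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_preprocess_json <- function(fitted, path) {
  jsonlite::write_json(fitted$params, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
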