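# Sparse partial least squares discriminant analysis: PLS2 with
# soft-thresholded X-weights so each latent component uses exactly keepX
# features, plus per-component AUC and VIP scores.

soft_threshold_keep <- function(a, keep) {
  if (keep >= length(a)) return(a)
  thr <- sort(abs(a), decreasing = TRUE)[keep + 1L]
  sign(a) * pmax(abs(a) - thr, 0)
}

#' Fit a sparse PLS-DA model
#'
#' Iterative PLS2 on the feature matrix against the centered class indicator
#' matrix. In each component the X-weight vector is soft-thresholded so that
#' exactly `keepX[c]` features carry nonzero weight, then normalized to unit
#' norm; `X` and `Y` are deflated between components. With `keepX = p` the
#' first component equals dense PLS-DA.
#'
#' @param x Numeric matrix/data.frame of features (standardized internally
#'   by default).
#' @param y Binary factor (second level = positive class).
#' @param ncomp Number of latent components (default 2).
#' @param keepX Integer vector, nonzero loadings per component (default
#'   `c(4, 4)`; recycled to `ncomp`).
#' @param scale Center and unit-scale columns before fitting (default TRUE).
#' @param max_iter,tol Inner-loop convergence controls (500, 1e-6).
#' @return Object of class `splsda_model`: sparse `weights` (p x ncomp),
#'   `scores` (n x ncomp), x/y loadings, deflated-matrix history norms,
#'   class centroids in score space, explained X- and Y-variance per
#'   component.
#' @export
fit_splsda <- function(x, y, ncomp = 2L, keepX = c(4L, 4L), scale = TRUE,
                       max_iter = 500L, tol = 1e-6) {
  xm <- as.matrix(x)
  p <- ncol(xm)
  keepX <- rep_len(as.integer(keepX), ncomp)
  if (any(keepX > p)) gs_param_error("keepX exceeds the number of features")
  if (any(keepX < 1L)) gs_param_error("keepX must be >= 1")
  y <- factor(y)
  if (nlevels(y) < 2L) gs_param_error("y must have two classes")
  center <- colMeans(xm)
  scl <- if (scale) apply(xm, 2L, stats::sd) else rep(1, p)
  if (any(scl == 0)) gs_param_error("constant feature column")
  X <- sweep(sweep(xm, 2L, center), 2L, scl, "/")
  Y <- stats::model.matrix(~ y - 1)
  Y <- sweep(Y, 2L, colMeans(Y))
  X0 <- X
  n <- nrow(X)
  W <- matrix(0, p, ncomp, dimnames = list(colnames(xm), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(xm), NULL))
  Q <- matrix(0, ncol(Y), ncomp)
  TT <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp); ssx <- numeric(ncomp)
  total_ssx <- sum(X^2); total_ssy <- sum(Y^2)
  for (h in seq_len(ncomp)) {
    u <- Y[, 1L]
    a_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      a <- drop(crossprod(X, u))
      a <- soft_threshold_keep(a, keepX[h])
      nrm <- sqrt(sum(a^2))
      if (nrm == 0) gs_param_error("degenerate component (all weights thresholded)")
      a <- a / nrm
      tt <- drop(X %*% a)
      b <- drop(crossprod(Y, tt))
      b <- b / sqrt(sum(b^2))
      u <- drop(Y %*% b)
      if (sqrt(sum((a - a_old)^2)) < tol) break
      a_old <- a
    }
    tt <- drop(X %*% a)
    t2 <- sum(tt^2)
    pl <- drop(crossprod(X, tt)) / t2
    ql <- drop(crossprod(Y, tt)) / t2
    X <- X - tcrossprod(tt, pl)
    Y <- Y - tcrossprod(tt, ql)
    W[, h] <- a; P[, h] <- pl; Q[, h] <- ql; TT[, h] <- tt
    ssx[h] <- t2 * sum(pl^2) / total_ssx
    ssy[h] <- t2 * sum(ql^2) / total_ssy
  }
  centroids <- lapply(setNames(levels(y), levels(y)), function(lv)
    colMeans(TT[y == lv, , drop = FALSE]))
  structure(list(weights = W, x_loadings = P, y_loadings = Q, scores = TT,
                 keepX = keepX, ncomp = ncomp, center = center, scale = scl,
                 levels = levels(y), centroids = centroids,
                 explained_x = ssx, explained_y = ssy,
                 residual_x_norm = sqrt(sum(X^2)),
                 y_classes = y),
            class = "splsda_model")
}

#' @export
print.splsda_model <- function(x, ...) {
  cat(sprintf("<splsda_model> %d components, keepX = %s, X-variance explained = %s\n",
              x$ncomp, paste(x$keepX, collapse = "/"),
              paste(sprintf("%.1f%%", 100 * x$explained_x), collapse = " + ")))
  invisible(x)
}

#' Project new samples onto sPLS-DA components
#'
#' @param object A `splsda_model`.
#' @param newdata Feature rows with the training columns.
#' @param ncomp Components to compute (default: all).
#' @param ... Unused.
#' @return Score matrix (n x ncomp).
#' @export
predict.splsda_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  X <- sweep(sweep(as.matrix(as.data.frame(newdata)[rownames(object$weights)]),
                   2L, object$center), 2L, object$scale, "/")
  TT <- matrix(0, nrow(X), ncomp)
  for (h in seq_len(ncomp)) {
    TT[, h] <- drop(X %*% object$weights[, h])
    X <- X - tcrossprod(TT[, h], object$x_loadings[, h])
  }
  TT
}

#' Per-component classification AUC of an sPLS-DA model
#'
#' Prediction score in the cumulative score space of the first `1..k`
#' components: the difference of Euclidean distances to the two training
#' class centroids. Returns the AUC for each component count.
#'
#' @param model A `splsda_model`.
#' @param x Feature rows.
#' @param y Binary labels.
#' @param up_to_component Largest component count (default: all fitted).
#' @return Named numeric vector `comp1, comp2, ...` of AUC values.
#' @export
component_auc <- function(model, x, y, up_to_component = model$ncomp) {
  y <- factor(y, levels = model$levels)
  if (nlevels(droplevels(y)) < 2L) gs_param_error("need both classes in y")
  TT <- predict(model, x)
  pos <- model$levels[2L]; neg <- model$levels[1L]
  out <- vapply(seq_len(up_to_component), function(k) {
    d_neg <- sqrt(rowSums((TT[, 1:k, drop = FALSE] -
      matrix(model$centroids[[neg]][1:k], nrow(TT), k, byrow = TRUE))^2))
    d_pos <- sqrt(rowSums((TT[, 1:k, drop = FALSE] -
      matrix(model$centroids[[pos]][1:k], nrow(TT), k, byrow = TRUE))^2))
    roc_auc(d_neg - d_pos, y)
  }, numeric(1))
  setNames(out, paste0("comp", seq_len(up_to_component)))
}

#' Variable importance in projection (VIP) scores
#'
#' Standard VIP: for feature j,
#' `VIP_j = sqrt( p * sum_c SS_c w_jc^2 / sum_c SS_c )` with unit-norm
#' component weights `w_c` and `SS_c` the Y-variance explained by component
#' c. The normalization makes `mean(VIP^2) = 1` over all p features.
#'
#' @param model A `splsda_model`.
#' @return Named numeric vector of VIP scores, sorted decreasing.
#' @export
vip_scores <- function(model) {
  W <- model$weights
  p <- nrow(W)
  ss <- model$explained_y
  vip <- sqrt(p * drop(W^2 %*% ss) / sum(ss))
  sort(setNames(vip, rownames(W)), decreasing = TRUE)
}

#' Export sPLS-DA artifacts as CSV
#'
#' Writes scores (+ class), sparse loadings and VIP scores — the plot data
#' for a sample-projection figure.
#'
#' @param model A `splsda_model`.
#' @param dir Output directory.
#' @param prefix File prefix (default `"splsda"`).
#' @return Invisibly, the paths written.
#' @export
write_splsda_csv <- function(model, dir, prefix = "splsda") {
  sc <- data.frame(model$scores)
  names(sc) <- paste0("comp", seq_len(model$ncomp))
  sc$class <- model$y_classes
  p1 <- file.path(dir, paste0(prefix, "_scores.csv"))
  p2 <- file.path(dir, paste0(prefix, "_loadings.csv"))
  p3 <- file.path(dir, paste0(prefix, "_vip.csv"))
  utils::write.csv(sc, p1, row.names = FALSE)
  utils::write.csv(data.frame(feature = rownames(model$weights), model$weights),
                   p2, row.names = FALSE)
  v <- vip_scores(model)
  utils::write.csv(data.frame(feature = names(v), vip = as.numeric(v)),
                   p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
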