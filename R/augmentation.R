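# Training-split augmentation. All augmenters operate in the standardized
# feature space, see only training rows, and mark every generated row with a
# provenance flag so synthetic data can never enter evaluation.

#' SMOTE: synthetic minority oversampling
#'
#' Each synthetic row is `x_i + u (x_nn - x_i)` with `u ~ Uniform(0, 1)` and
#' `x_nn` one of the `k` nearest minority neighbours of `x_i` (Euclidean
#' distance in the standardized space), so every generated point lies on a
#' segment between two minority rows.
#'
#' @param x_minority Matrix/data.frame of minority-class rows (standardized).
#' @param n_synth Number of synthetic rows to generate.
#' @param k Neighbourhood size (default 5; reduced with a warning when the
#'   minority class has `<= k` rows).
#' @param seed Integer seed.
#' @return Matrix of `n_synth` synthetic rows (0-row matrix when
#'   `n_synth = 0`), with attribute `base_index` giving the seed row of each.
#' @export
smote <- function(x_minority, n_synth, k = 5L, seed = 1L) {
  xm <- as.matrix(x_minority)
  n <- nrow(xm)
  if (n < 2L) gs_param_error("SMOTE needs at least 2 minority rows")
  if (n <= k) {
    warning(sprintf("minority count %d <= k = %d; using k = %d", n, k, n - 1L))
    k <- n - 1L
  }
  if (n_synth == 0L)
    return(structure(xm[integer(0), , drop = FALSE], base_index = integer(0)))
  dm <- as.matrix(stats::dist(xm))
  diag(dm) <- Inf
  nn_idx <- t(apply(dm, 1L, function(d) order(d)[seq_len(k)]))
  with_seed(seed, {
    base <- sample.int(n, n_synth, replace = TRUE)
    pick <- nn_idx[cbind(base, sample.int(k, n_synth, replace = TRUE))]
    u <- runif(n_synth)
    out <- xm[base, , drop = FALSE] +
      u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    structure(out, base_index = base)
  })
}

# --- minimal Adam-optimized adversarial pair -------------------------------

adam_step <- function(state, grads, lr = 2e-3, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    state$par[[nm]] <- state$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

adam_init <- function(par) {
  list(par = par, m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0L)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# train one small generator/discriminator pair on rows of x (class-specific).
# Generator: z -> tanh(W1 z + b1) -> W2 h + b2; discriminator mirrors it.
# The generator loss adds a feature-matching term (match batch means) which
# stabilizes training on small tabular data.
train_gan_class <- function(x, epochs = 400L, hidden = 16L, batch = 32L,
                            lr = 2e-3, fm_weight = 1) {
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) gs_param_error("cannot train a generator on a single-row class")
  dz <- p
  init <- function(r, c) matrix(rnorm(r * c, sd = 0.2), r, c)
  # output bias starts at the class mean so adversarial training refines an
  # already-centred generator
  G <- adam_init(list(W1 = init(hidden, dz), b1 = matrix(0, hidden, 1),
                      W2 = init(p, hidden), b2 = matrix(colMeans(x), p, 1)))
  D <- adam_init(list(V1 = init(hidden, p), c1 = matrix(0, hidden, 1),
                      v2 = init(1, hidden), c2 = matrix(0, 1, 1)))
  gen_forward <- function(par, z) {
    h <- tanh(par$W1 %*% z + par$b1[, rep(1, ncol(z)), drop = FALSE])
    list(h = h, out = par$W2 %*% h + par$b2[, rep(1, ncol(z)), drop = FALSE])
  }
  disc_forward <- function(par, xb) {
    h <- tanh(par$V1 %*% xb + par$c1[, rep(1, ncol(xb)), drop = FALSE])
    list(h = h, logit = as.numeric(par$v2 %*% h + par$c2[1, 1]))
  }
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n, min(batch, n))
    xr <- t(x[idx, , drop = FALSE])            # p x b
    b <- ncol(xr)
    z <- matrix(rnorm(dz * b), dz, b)
    gf <- gen_forward(G$par, z)
    xf <- gf$out
    # --- discriminator update (real = 1, fake = 0)
    dr <- disc_forward(D$par, xr); df <- disc_forward(D$par, xf)
    er <- sigmoid(dr$logit) - 1                # dL/dlogit, real batch
    ef <- sigmoid(df$logit)                    # fake batch
    grad_D <- function(fw, e, xin) {
      dh <- (D$par$v2[1, ] %o% e) * (1 - fw$h^2)   # hidden x b
      list(V1 = dh %*% t(xin) / b, c1 = matrix(rowMeans(dh)),
           v2 = matrix(fw$h %*% e / b, 1), c2 = matrix(mean(e)))
    }
    gr <- grad_D(dr, er, xr); gg <- grad_D(df, ef, xf)
    D <- adam_step(D, Map(`+`, gr, gg), lr = lr)
    if (!all(vapply(D$par, function(p) all(is.finite(p)), logical(1))))
      gs_stop("discriminator diverged (non-finite parameters)", "gaitstab_gan_error")
    # --- generator update (non-saturating + feature matching)
    z <- matrix(rnorm(dz * b), dz, b)
    gf <- gen_forward(G$par, z)
    df <- disc_forward(D$par, gf$out)
    e_adv <- sigmoid(df$logit) - 1             # dL/dlogit for -log D(G(z))
    dh_d <- (D$par$v2[1, ] %o% e_adv) * (1 - df$h^2)
    dx_adv <- t(D$par$V1) %*% dh_d / b         # p x b
    # feature matching on first and second marginal moments
    fm <- rowMeans(gf$out) - colMeans(x[idx, , drop = FALSE])
    dx_fm <- fm_weight * 2 * fm %o% rep(1 / b, b)
    fm2 <- rowMeans(gf$out^2) - colMeans(x[idx, , drop = FALSE]^2)
    dx_fm2 <- fm_weight * 4 * (fm2 %o% rep(1 / b, b)) * gf$out
    dx <- dx_adv + dx_fm + dx_fm2
    dh_g <- (t(G$par$W2) %*% dx) * (1 - gf$h^2)
    grads_G <- list(W1 = dh_g %*% t(z), b1 = matrix(rowSums(dh_g)),
                    W2 = dx %*% t(gf$h), b2 = matrix(rowSums(dx)))
    G <- adam_step(G, grads_G, lr = lr)
    if (!all(vapply(G$par, function(p) all(is.finite(p)), logical(1))))
      gs_stop("generator diverged (non-finite parameters)", "gaitstab_gan_error")
  }
  list(par = G$par, dz = dz,
       sample = function(n_out) {
     z <- matrix(rnorm(dz * n_out), dz, n_out)
     t(gen_forward(G$par, z)$out)
   })
}

# per-class conditional Gaussian with shrinkage covariance
fit_cond_gaussian <- function(x) {
  if (nrow(x) < 2L) gs_param_error("cannot fit a generator on a single-row class")
  mu <- colMeans(x)
  S <- stats::cov(x)
  S <- 0.9 * S + 0.1 * diag(diag(S), ncol(x))
  diag(S) <- diag(S) + 1e-8
  R <- chol(S)
  list(mu = mu, chol = R,
       sample = function(n_out)
         matrix(rnorm(n_out * length(mu)), n_out) %*% R +
           matrix(mu, n_out, length(mu), byrow = TRUE))
}

#' Fit a pluggable tabular generator for augmentation
#'
#' `kind = "gan"` trains a lightweight fully-connected adversarial pair
#' (one hidden layer each, feature-matching stabilizer) per class;
#' `kind = "ctgan"` fits a per-class conditional Gaussian sampler with a
#' shrinkage covariance. Both honour the same contract: a `tabular_generator`
#' whose samples are drawn per class via [sample_synthetic()]. After fitting,
#' a quality gate checks that per-feature sample means lie within 0.5 training
#' SD of the training marginals (and SDs within a factor of 2); violations
#' warn but do not fail.
#'
#' @param x_train Matrix/data.frame of standardized training features.
#' @param labels Class label per row.
#' @param kind `"gan"` or `"ctgan"`.
#' @param seed Integer seed.
#' @param epochs GAN training epochs (default 400).
#' @return A `tabular_generator` object.
#' @export
fit_tabular_generator <- function(x_train, labels, kind = c("gan", "ctgan"),
                                  seed = 1L, epochs = 400L) {
  kind <- match.arg(kind)
  xm <- as.matrix(x_train)
  labels <- as.character(labels)
  classes <- unique(labels)
  fits <- with_seed(seed, {
    lapply(setNames(classes, classes), function(cl) {
      xc <- xm[labels == cl, , drop = FALSE]
      if (kind == "gan") train_gan_class(xc, epochs = epochs) else fit_cond_gaussian(xc)
    })
  })
  gen <- structure(list(kind = kind, fits = fits, seed = seed,
                        classes = classes, p = ncol(xm),
                        colnames = colnames(xm),
                        train_mean = lapply(setNames(classes, classes), function(cl)
                          colMeans(xm[labels == cl, , drop = FALSE])),
                        train_sd = lapply(setNames(classes, classes), function(cl)
                          apply(xm[labels == cl, , drop = FALSE], 2, stats::sd))),
                   class = "tabular_generator")
  # quality gate on 200 draws per class
  gate <- lapply(setNames(classes, classes), function(cl) {
    s <- sample_synthetic(gen, 200L, cl, seed = seed + 7L)
    dm <- abs(colMeans(s) - gen$train_mean[[cl]]) / pmax(gen$train_sd[[cl]], 1e-8)
    dsd <- apply(s, 2, stats::sd) / pmax(gen$train_sd[[cl]], 1e-8)
    list(mean_shift_sd = dm, sd_ratio = dsd,
         pass = all(dm <= 0.5) && all(dsd >= 0.5 & dsd <= 2))
  })
  gen$quality_gate <- gate
  if (!all(vapply(gate, `[[`, logical(1), "pass")))
    warning("tabular generator quality gate: sample marginals deviate from training marginals")
  gen
}

#' Draw synthetic rows from a fitted tabular generator
#'
#' @param generator A `tabular_generator` from [fit_tabular_generator()].
#' @param n Number of rows.
#' @param class Class label to condition on.
#' @param seed Integer seed.
#' @return Matrix of `n` synthetic rows.
#' @export
sample_synthetic <- function(generator, n, class, seed = 1L) {
  stopifnot(inherits(generator, "tabular_generator"))
  if (!class %in% generator$classes) gs_param_error("unknown class")
  if (n == 0L) {
    out <- matrix(numeric(0), 0L, generator$p)
    colnames(out) <- generator$colnames
    return(out)
  }
  out <- with_seed(seed, generator$fits[[class]]$sample(n))
  colnames(out) <- generator$colnames
  out
}

#' @export
print.tabular_generator <- function(x, ...) {
  ok <- all(vapply(x$quality_gate, `[[`, logical(1), "pass"))
  cat(sprintf("<tabular_generator> kind = %s, classes = %s, quality gate %s\n",
              x$kind, paste(x$classes, collapse = "/"),
              if (ok) "passed" else "FLAGGED"))
  invisible(x)
}

# how many synthetic rows per class for a target-size rule
synth_counts <- function(counts, target_size) {
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(names(counts), minority)
  add <- setNames(c(0L, 0L), c(minority, majority))
  if (target_size == "balance100") {
    add[minority] <- max(0L, 100L - counts[[minority]])
  } else if (target_size %in% c("N200", "N1000")) {
    total <- if (target_size == "N200") 200L else 1000L
    bal <- min(total, max(0L, counts[[majority]] - counts[[minority]]))
    add[minority] <- bal
    rest <- total - bal
    add[minority] <- add[minority] + ceiling(rest / 2)
    add[majority] <- floor(rest / 2)
  } else gs_param_error("unknown target size rule")
  add
}

#' Augment a training split (test rows untouched)
#'
#' Generates synthetic rows for the training split only, using SMOTE or a
#' fitted tabular generator, under one of three size rules: `"balance100"`
#' (raise the minority class to 100 rows, the design condition for the
#' imbalanced 71/39 cohort), `"N200"` or `"N1000"` (add 200 / 1000 synthetic
#' rows in total, balancing the classes first). Every synthetic row carries
#' `is_synthetic = TRUE`; the test split is returned bit-for-bit unchanged.
#'
#' @param split List with `train` and `test` data.frames, a `label_col`
#'   factor column, and numeric feature columns `feature_cols`.
#' @param method `"none"`, `"smote"`, `"gan"` or `"ctgan"`.
#' @param target_size `"balance100"`, `"N200"` or `"N1000"`.
#' @param label_col Name of the class column (default `"group"`).
#' @param feature_cols Feature columns (default: all numeric columns).
#' @param seed Integer seed.
#' @param generator Optional pre-fitted `tabular_generator` (must have been
#'   fitted on the training rows only).
#' @return List `train` (augmented, with `is_synthetic` flag), `test`
#'   (unchanged), `method`, `target_size`.
#' @export
augment_training_split <- function(split, method = c("none", "smote", "gan", "ctgan"),
                                   target_size = "balance100",
                                   label_col = "group", feature_cols = NULL,
                                   seed = 1L, generator = NULL) {
  method <- match.arg(method)
  train <- split$train; test <- split$test
  if (is.null(feature_cols))
    feature_cols <- names(train)[vapply(train, is.numeric, logical(1))]
  train$is_synthetic <- FALSE
  if (!is.null(test)) test$is_synthetic <- FALSE
  if (method == "none")
    return(list(train = train, test = test, method = method,
                target_size = target_size))
  y <- train[[label_col]]
  counts <- table(as.character(y))
  add <- synth_counts(counts, target_size)
  if (method %in% c("gan", "ctgan") && is.null(generator))
    generator <- fit_tabular_generator(train[feature_cols], y, kind = method,
                                       seed = seed)
  new_rows <- list()
  for (cl in names(add)) {
    if (add[[cl]] == 0L) next
    xs <- if (method == "smote") {
      smote(train[y == cl, feature_cols, drop = FALSE], n_synth = add[[cl]],
            seed = seed + match(cl, names(add)))
    } else {
      sample_synthetic(generator, add[[cl]], cl, seed = seed + match(cl, names(add)))
    }
    d <- as.data.frame(xs)
    names(d) <- feature_cols
    d[[label_col]] <- factor(cl, levels = levels(y))
    d$is_synthetic <- TRUE
    new_rows[[cl]] <- d
  }
  if (length(new_rows)) {
    extra <- do.call(rbind, new_rows)
    for (cn in setdiff(names(train), names(extra))) extra[[cn]] <- NA
    train <- rbind(train, extra[names(train)])
  }
  rownames(train) <- NULL
  list(train = train, test = test, method = method, target_size = target_size,
       generator = generator)
}
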