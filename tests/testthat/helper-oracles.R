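# Independent brute-force oracles, written from the metric definitions and
# kept free of any package internals.

# O(n^2) sample entropy: explicit double loop over template pairs
sampen_oracle <- function(x, m = 2L, r) {
  n <- length(x)
  nt <- n - m
  a <- 0L; b <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      dm <- max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)]))
      if (dm <= r) {
        b <- b + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) a <- a + 1L
      }
    }
  }
  list(a = a, b = b, sampen = -log(a / b))
}

# brute-force recurrence analysis: explicit embedding, full distance matrix,
# diagonal census by scanning every diagonal of the recurrence matrix
rqa_oracle <- function(x, dim, delay, radius, lmin, theiler) {
  n_pts <- length(x) - (dim - 1L) * delay
  emb <- matrix(0, n_pts, dim)
  for (i in seq_len(n_pts))
    for (k in seq_len(dim))
      emb[i, k] <- x[i + (k - 1L) * delay]
  rec <- matrix(FALSE, n_pts, n_pts)
  for (i in seq_len(n_pts))
    for (j in seq_len(n_pts))
      rec[i, j] <- sqrt(sum((emb[i, ] - emb[j, ])^2)) <= radius
  valid <- abs(row(rec) - col(rec)) > theiler
  n_rec <- sum(rec & valid)
  pct_rec <- 100 * n_rec / sum(valid)
  if (n_rec == 0L) return(c(rec = pct_rec, det = NA_real_))
  diag_pts <- 0L
  countable <- 0L
  for (k in (theiler + 1L):(n_pts - lmin)) {
    run <- 0L
    for (i in seq_len(n_pts - k)) {
      if (rec[i, i + k]) { run <- run + 1L; countable <- countable + 1L }
      if (!rec[i, i + k] || i == n_pts - k) {
        if (run >= lmin) diag_pts <- diag_pts + run
        run <- 0L
      }
    }
  }
  c(rec = pct_rec, det = 100 * diag_pts / countable)
}

# rank-sum AUC oracle via explicit pair counting
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# shared small fixtures
make_two_class_matrix <- function(n = 120, p = 10, n_inform = 4, d = 1.2,
                                  seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("HC", "PwS"), each = n / 2))
  mu <- c(rep(d, n_inform), rep(0, p - n_inform))
  x <- matrix(rnorm(n * p), n) + outer(as.numeric(y) - 1, mu)
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y, informative = paste0("f", seq_len(n_inform)))
}

default_reg_predictors <- function() {
  c("even_speed", "Ang_IC_ankle", "even_HR_AP", "even_RMS_VT",
    "even_SampEn_AP", "CI_TA_SOL_stance", "age")
}
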