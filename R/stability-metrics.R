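# Linear and nonlinear trunk-acceleration stability indicators.
#
# All metrics operate on demeaned windows; SampEn and RQA use raw sample
# spacing, while the short-term Lyapunov exponent is computed on a
# time-normalized series (fixed samples per stride) so that estimates are
# comparable across walking speeds.

#' Configuration for the stability metrics
#'
#' Bundles every tunable parameter of the nonlinear metrics. Defaults follow
#' field conventions: sample entropy with embedding length m = 2 and tolerance
#' r = 0.2 x SD; recurrence analysis with embedding dimension 5, delay 10
#' samples, radius 0.4 x signal SD and minimum diagonal length 2; the
#' Rosenstein short-term Lyapunov exponent on 100 samples/stride with the
#' divergence slope fitted over the first half stride; harmonic ratio over the
#' first 20 stride-frequency harmonics.
#'
#' @param sampen_m Sample-entropy template length (default 2).
#' @param sampen_r Sample-entropy tolerance as a multiple of the series SD
#'   (default 0.2).
#' @param rqa_dim,rqa_delay Embedding dimension and delay (samples) for
#'   recurrence analysis (defaults 5, 10).
#' @param rqa_radius_factor Recurrence radius as a multiple of the series SD
#'   (default 0.4).
#' @param rqa_min_diag Minimum diagonal line length counted as deterministic
#'   (default 2).
#' @param sle_dim,sle_delay Embedding dimension and delay for the Lyapunov
#'   estimator (defaults 5, 10).
#' @param sle_samples_per_stride Samples per stride after time normalization
#'   (default 100).
#' @param sle_fit_fraction Fraction of one stride over which the divergence
#'   slope is fitted (default 0.5, the standard short-term window).
#' @param hr_n_harmonics Number of stride-frequency harmonics entering the
#'   harmonic ratio (default 20).
#' @return A list of class `metric_config`.
#' @export
metric_config <- function(sampen_m = 2L, sampen_r = 0.2,
                          rqa_dim = 5L, rqa_delay = 10L,
                          rqa_radius_factor = 0.4, rqa_min_diag = 2L,
                          sle_dim = 5L, sle_delay = 10L,
                          sle_samples_per_stride = 100L, sle_fit_fraction = 0.5,
                          hr_n_harmonics = 20L) {
  cfg <- list(sampen_m = as.integer(sampen_m), sampen_r = sampen_r,
              rqa_dim = as.integer(rqa_dim), rqa_delay = as.integer(rqa_delay),
              rqa_radius_factor = rqa_radius_factor,
              rqa_min_diag = as.integer(rqa_min_diag),
              sle_dim = as.integer(sle_dim), sle_delay = as.integer(sle_delay),
              sle_samples_per_stride = as.integer(sle_samples_per_stride),
              sle_fit_fraction = sle_fit_fraction,
              hr_n_harmonics = as.integer(hr_n_harmonics))
  with(cfg, {
    if (sampen_m < 1L || sampen_r <= 0) gs_param_error("invalid sample-entropy config")
    if (rqa_dim < 1L || rqa_delay < 1L || rqa_radius_factor <= 0 || rqa_min_diag < 2L)
      gs_param_error("invalid RQA config")
    if (sle_dim < 1L || sle_delay < 1L || sle_samples_per_stride < 10L ||
        sle_fit_fraction <= 0 || sle_fit_fraction > 1)
      gs_param_error("invalid Lyapunov config")
    if (hr_n_harmonics < 2L) gs_param_error("hr_n_harmonics must be >= 2")
  })
  structure(cfg, class = "metric_config")
}

#' Speed-normalized root mean square of a demeaned acceleration window
#'
#' `sqrt(mean(x^2))` of the demeaned window divided by the squared gait speed,
#' removing the strong mechanical dependence of trunk acceleration amplitude on
#' walking speed.
#'
#' @param window Numeric vector (acceleration, m/s^2); demeaned internally.
#' @param speed Gait speed in m/s (> 0).
#' @return Unitless normalized RMS (m/s^2 per (m/s)^2).
#' @examples
#' rms_normalized(sin(seq(0, 20 * pi, length.out = 2000)), speed = 1)
#' @export
rms_normalized <- function(window, speed) {
  if (!is_scalar_num(speed) || speed <= 0) gs_param_error("speed must be positive")
  x <- window - mean(window)
  sqrt(mean(x^2)) / speed^2
}

# amplitude of the discrete Fourier component at frequency f (Hz)
dft_amplitude <- function(x, f, fs) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  Mod(sum(x * exp(-2i * pi * f * t))) * 2 / n
}

#' Harmonic ratio of a gait acceleration window
#'
#' Evaluates the amplitude spectrum at the first `n_harmonics` integer
#' multiples of the stride frequency. For the AP and VT axes (dominated by the
#' step frequency, i.e. even stride harmonics) the ratio is the even-harmonic
#' amplitude sum over the odd; for ML (dominated by odd harmonics) the inverse.
#' Higher values indicate a smoother, more symmetric gait pattern.
#'
#' @param window Numeric vector spanning an integer number of strides
#'   (demeaned internally).
#' @param stride_freq Stride frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param axis One of "AP", "ML", "VT".
#' @param n_harmonics Number of harmonics (default 20).
#' @return The harmonic ratio; `Inf` with attribute `degenerate = TRUE` when
#'   the denominator sum is numerically zero.
#' @export
harmonic_ratio <- function(window, stride_freq, fs, axis = c("AP", "ML", "VT"),
                           n_harmonics = 20L) {
  axis <- match.arg(axis)
  if (!is_scalar_num(stride_freq) || stride_freq <= 0)
    gs_param_error("stride_freq must be positive")
  x <- window - mean(window)
  amps <- vapply(seq_len(n_harmonics),
                 function(k) dft_amplitude(x, k * stride_freq, fs), numeric(1))
  even <- sum(amps[seq(2, n_harmonics, by = 2)])
  odd <- sum(amps[seq(1, n_harmonics, by = 2)])
  num <- if (axis == "ML") odd else even
  den <- if (axis == "ML") even else odd
  if (den <= .Machine$double.eps * max(num, 1)) {
    return(structure(Inf, degenerate = TRUE))
  }
  num / den
}

#' Sample entropy
#'
#' The negative log conditional probability that two sequences matching for
#' `m` points (Chebyshev distance within `r = r_factor x SD`) also match for
#' `m + 1` points; self-matches excluded. Higher values indicate a more
#' irregular signal.
#'
#' @param x Numeric series (at least ~200 samples for stable estimates).
#' @param m Template length (default 2).
#' @param r_factor Tolerance as a multiple of `sd(x)` (default 0.2).
#' @return Sample entropy in nats; `NA` with attribute `degenerate = TRUE`
#'   when no template matches exist at length `m + 1`.
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.2) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < m + 2L) gs_param_error("series too short for sample entropy")
  r <- r_factor * stats::sd(x)
  nt <- n - m  # templates of length m+1 exist for i = 1..n-m
  # Chebyshev distances built incrementally from the scalar distance matrix
  d1 <- abs(outer(x, x, "-"))
  cheb <- d1[seq_len(nt), seq_len(nt)]
  for (k in seq_len(m - 1L)) {
    cheb <- pmax(cheb, d1[seq_len(nt) + k, seq_len(nt) + k])
  }
  ut <- upper.tri(cheb)
  b_count <- sum(cheb[ut] <= r)
  cheb_a <- pmax(cheb, d1[seq_len(nt) + m, seq_len(nt) + m])
  a_count <- sum(cheb_a[ut] <= r)
  if (b_count == 0L || a_count == 0L) {
    if (b_count > 0L && a_count == 0L)
      return(structure(NA_real_, degenerate = TRUE))
    if (b_count == 0L) return(structure(NA_real_, degenerate = TRUE))
  }
  -log(a_count / b_count)
}

# delay embedding: rows are state-space points
delay_embed <- function(x, dim, delay) {
  n <- length(x) - (dim - 1L) * delay
  if (n < 2L) gs_param_error("embedding longer than series")
  sapply(seq_len(dim), function(k) x[seq_len(n) + (k - 1L) * delay])
}

#' Recurrence quantification of a gait acceleration window
#'
#' Time-delay embedding followed by a recurrence matrix (Euclidean distance
#' within `radius = rqa_radius_factor x SD`). `%REC` is the recurrent fraction
#' outside a Theiler window equal to the embedding delay; `%DET` the fraction
#' of recurrent points lying on diagonal lines of length at least
#' `rqa_min_diag` (periodicity / determinism), counted over the diagonals
#' long enough to hold such a line.
#'
#' @param x Numeric series.
#' @param config A [metric_config].
#' @return Named numeric vector `c(rec = %REC, det = %DET)`; `det` is `NA`
#'   when no recurrent points exist.
#' @export
rqa <- function(x, config = metric_config()) {
  x <- as.numeric(x)
  d <- config$rqa_dim; tau <- config$rqa_delay
  lmin <- config$rqa_min_diag
  if (length(x) <= (d - 1L) * tau + lmin)
    gs_param_error("series too short for the requested embedding")
  emb <- delay_embed(x, d, tau)
  m <- nrow(emb)
  # radius in the embedded space: the Euclidean norm grows with sqrt(dim),
  # so the SD-fraction radius is scaled accordingly
  radius <- config$rqa_radius_factor * stats::sd(x) * sqrt(d)
  dm <- as.matrix(stats::dist(emb))
  rec_mat <- dm <= radius
  theiler <- tau
  lag <- abs(row(dm) - col(dm))
  valid <- lag > theiler
  n_valid <- sum(valid)
  n_rec <- sum(rec_mat & valid)
  rec <- 100 * n_rec / n_valid
  if (n_rec == 0L) return(c(rec = rec, det = NA_real_))
  # diagonal-line census over both triangles (symmetric); diagonals shorter
  # than the minimum line length can never hold a deterministic line, so
  # they are excluded from the determinism denominator as well
  n_diag_pts <- 0L
  n_countable <- 0L
  for (k in (theiler + 1L):(m - lmin)) {
    diag_line <- rec_mat[cbind(seq_len(m - k), seq_len(m - k) + k)]
    n_countable <- n_countable + sum(diag_line)
    runs <- rle(diag_line)
    long <- runs$values & runs$lengths >= lmin
    n_diag_pts <- n_diag_pts + sum(runs$lengths[long])
  }
  if (n_countable == 0L) return(c(rec = rec, det = NA_real_))
  c(rec = rec, det = 100 * n_diag_pts / n_countable)
}

# linear interpolation of one gait cycle onto n points
resample_cycle <- function(x, n) {
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n))$y
}

# time-normalize a windowed series to a fixed number of samples per stride
time_normalize_strides <- function(x, boundaries, samples_per_stride) {
  out <- lapply(seq_len(length(boundaries) - 1L), function(k) {
    seg <- x[boundaries[k]:(boundaries[k + 1L] - 1L)]
    resample_cycle(seg, samples_per_stride)
  })
  unlist(out)
}

#' Short-term maximum Lyapunov exponent (Rosenstein method)
#'
#' The window is first time-normalized to `sle_samples_per_stride` samples per
#' stride (removing the walking-speed confound), delay-embedded, and for each
#' state-space point the nearest neighbour outside a temporal exclusion of one
#' mean period is found. The estimator is the least-squares slope of the mean
#' log-divergence curve over the first `sle_fit_fraction` of a stride,
#' expressed in nats per stride. Larger values indicate poorer local dynamic
#' stability.
#'
#' @param x Numeric series covering whole gait cycles.
#' @param boundaries Integer sample indices of cycle starts within `x`
#'   (length `n_strides + 1`, last = one past the final sample of the window).
#' @param config A [metric_config].
#' @return Divergence exponent in nats/stride; `NA` with attribute
#'   `degenerate = TRUE` when no valid neighbours exist.
#' @export
short_term_lyapunov <- function(x, boundaries, config = metric_config()) {
  sps <- config$sle_samples_per_stride
  z <- time_normalize_strides(as.numeric(x), boundaries, sps)
  emb <- delay_embed(z, config$sle_dim, config$sle_delay)
  m <- nrow(emb)
  period <- sps
  if (m <= 2L * period) return(structure(NA_real_, degenerate = TRUE))
  dm <- as.matrix(stats::dist(emb))
  lag <- abs(row(dm) - col(dm))
  dm[lag <= period] <- Inf
  nn <- apply(dm, 1L, which.min)
  k_max <- max(1L, floor(config$sle_fit_fraction * sps))
  # distance floor relative to signal scale: exactly-periodic trajectories
  # give a flat divergence curve instead of numerical-noise logs
  eps0 <- 1e-10 * max(stats::sd(z), .Machine$double.eps)
  mean_log_div <- vapply(0:k_max, function(k) {
    i <- seq_len(m)
    ok <- (i + k) <= m & (nn + k) <= m & is.finite(dm[cbind(i, nn)])
    if (!any(ok)) return(NA_real_)
    dk <- sqrt(rowSums((emb[i[ok] + k, , drop = FALSE] -
                          emb[nn[ok] + k, , drop = FALSE])^2))
    mean(log(pmax(dk, eps0)))
  }, numeric(1))
  ok <- is.finite(mean_log_div)
  if (sum(ok) < 2L) return(structure(NA_real_, degenerate = TRUE))
  kk <- (0:k_max)[ok]
  slope_per_sample <- stats::coef(stats::lm(mean_log_div[ok] ~ kk))[[2L]]
  slope_per_sample * sps
}

#' Compute the full stability feature set for one subject window
#'
#' Applies all six indicators (speed-normalized RMS, harmonic ratio, sample
#' entropy, recurrence %REC and %DET, short-term Lyapunov exponent) to the
#' AP, ML and VT axes of an extracted stride window.
#'
#' @param strides A `stride_series` from [extract_cycles()].
#' @param speed Gait speed in m/s (for RMS normalization).
#' @param config A [metric_config].
#' @return A one-row `data.frame` with 18 canonical columns
#'   (`RMS_AP`, ..., `sLE_VT`); the configuration used is attached as
#'   attribute `config`. Degenerate metrics appear as `NA`.
#' @export
compute_stability_features <- function(strides, speed, config = metric_config()) {
  stopifnot(inherits(strides, "stride_series"))
  stride_freq <- 1 / strides$mean_stride_time
  axes <- c(AP = "ap", ML = "ml", VT = "vt")
  out <- list()
  for (ax in names(axes)) {
    w <- strides[[axes[[ax]]]]
    w <- w - mean(w)
    out[[paste0("RMS_", ax)]] <- rms_normalized(w, speed)
    out[[paste0("HR_", ax)]] <- as.numeric(harmonic_ratio(
      w, stride_freq, strides$fs, axis = ax, n_harmonics = config$hr_n_harmonics))
    out[[paste0("SampEn_", ax)]] <- as.numeric(sample_entropy(
      w, m = config$sampen_m, r_factor = config$sampen_r))
    rq <- rqa(w, config)
    out[[paste0("RQA_rec_", ax)]] <- rq[["rec"]]
    out[[paste0("RQA_det_", ax)]] <- rq[["det"]]
    out[[paste0("sLE_", ax)]] <- as.numeric(short_term_lyapunov(
      w, strides$boundaries, config))
  }
  res <- as.data.frame(out)
  attr(res, "config") <- config
  res
}

#' Canonical stability-feature column names
#' @return Character vector of the 18 metric names (6 metrics x 3 axes).
#' @export
stability_feature_names <- function() {
  as.vector(outer(c("RMS", "HR", "SampEn", "RQA_rec", "RQA_det", "sLE"),
                  c("AP", "ML", "VT"), paste, sep = "_"))
}
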