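# Even-surface EMG and joint-angle predictors: envelope extraction,
# co-contraction indices, zero-lag angle filtering and 100-point cycle
# normalization.

#' EMG linear envelope
#'
#' Applies the conventional chain in order: band-pass 20-500 Hz (4th-order
#' Butterworth, zero-lag; the upper edge is clipped below Nyquist with a
#' warning when the sampling rate is too low), mean-centering, full-wave
#' rectification, 10 Hz low-pass (zero-lag), then normalization to the
#' individual's maximum amplitude.
#'
#' @param raw Numeric vector of raw EMG.
#' @param fs Sampling rate in Hz.
#' @param band Band-pass edges in Hz (default `c(20, 500)`).
#' @param lowpass Envelope low-pass cutoff in Hz (default 10).
#' @return Envelope in `[0, 1]` with attribute `fs`.
#' @export
emg_envelope <- function(raw, fs, band = c(20, 500), lowpass = 10) {
  if (!is_scalar_num(fs) || fs <= 2 * band[1L])
    gs_param_error("sampling rate too low for the band-pass filter")
  nyq <- fs / 2
  if (band[2L] >= nyq) {
    warning(sprintf("band upper edge clipped to %.0f Hz (Nyquist %.0f Hz)",
                    0.95 * nyq, nyq))
    band[2L] <- 0.95 * nyq
  }
  bp <- signal::butter(4, band / nyq, type = "pass")
  x <- signal::filtfilt(bp, raw - mean(raw))
  x <- x - mean(x)
  x <- abs(x)
  lp <- signal::butter(4, lowpass / nyq, type = "low")
  env <- signal::filtfilt(lp, x)
  env <- pmax(env, 0)
  mx <- max(env)
  if (mx <= 1e-8 * max(abs(raw), 1)) {
    if (all(raw == 0))
      gs_param_error("all-zero input: cannot normalize envelope")
    # e.g. a pure-DC channel: mean-centering removes everything
    warning("no activity detected after filtering; normalization skipped")
    return(structure(env, fs = fs))
  }
  structure(env / mx, fs = fs)
}

#' Co-contraction index of two normalized envelopes over a gait phase
#'
#' Falconer-Winter style overlap:
#' `CI = 100 * 2 * sum(min(e1, e2)) / sum(e1 + e2)` over the samples of the
#' requested phase. 100 means identical activation, 0 temporally disjoint
#' activation.
#'
#' @param e1,e2 Equal-length cycle-normalized envelope curves.
#' @param phase `"stance"`, `"swing"` or `"all"`.
#' @param stance_end Index of the stance/swing boundary within the curves
#'   (default 60, i.e. toe-off at 60 % of the cycle on a 100-point curve).
#' @return CI in percent; `NA` with attribute `degenerate = TRUE` when both
#'   envelopes are zero over the phase.
#' @export
cocontraction_index <- function(e1, e2, phase = c("stance", "swing", "all"),
                                stance_end = 60L) {
  phase <- match.arg(phase)
  if (length(e1) != length(e2)) gs_param_error("curves must have equal length")
  idx <- switch(phase,
                stance = seq_len(min(stance_end, length(e1))),
                swing = (min(stance_end, length(e1)) + 1L):length(e1),
                all = seq_along(e1))
  den <- sum(e1[idx] + e2[idx])
  if (den == 0) return(structure(NA_real_, degenerate = TRUE))
  100 * 2 * sum(pmin(e1[idx], e2[idx])) / den
}

#' Zero-lag low-pass filtering of joint-angle series
#'
#' Forward-backward (zero-phase) 4th-order Butterworth low-pass at `cutoff`
#' Hz, the standard smoothing for sagittal joint angles.
#'
#' @param raw Numeric angle series (degrees).
#' @param fs Sampling rate in Hz (> 2 x cutoff).
#' @param cutoff Low-pass cutoff in Hz (default 6).
#' @return Filtered series.
#' @export
filter_angles <- function(raw, fs, cutoff = 6) {
  if (!is_scalar_num(fs) || fs <= 2 * cutoff)
    gs_param_error("fs must exceed twice the cutoff")
  if (length(raw) < 24L)
    gs_param_error("series shorter than the filter pad length")
  lp <- signal::butter(4, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(lp, raw))
}

#' Time-normalize a series to 100 points per gait cycle
#'
#' Linearly interpolates each IC-to-IC cycle onto 100 points and averages
#' across cycles, yielding one cycle-normalized curve with its stance/swing
#' boundary (from the mean relative toe-off time).
#'
#' @param x Numeric series.
#' @param events A [gait_events] covering `x`.
#' @return List of class `cycle_curve`: `curve` (length 100), `stance_end`
#'   (boundary index), `n_cycles`.
#' @export
time_normalize <- function(x, events) {
  stopifnot(inherits(events, "gait_events"))
  ic <- events$ic_indices
  curves <- sapply(seq_len(length(ic) - 1L), function(k)
    resample_cycle(x[ic[k]:(ic[k + 1L] - 1L)], 100L))
  to_rel <- vapply(seq_len(length(ic) - 1L), function(k) {
    tos <- events$to_indices[events$to_indices > ic[k] &
                               events$to_indices < ic[k + 1L]]
    if (length(tos) == 0L) return(NA_real_)
    (tos[1L] - ic[k]) / (ic[k + 1L] - ic[k])
  }, numeric(1))
  stance_end <- round(100 * mean(to_rel, na.rm = TRUE))
  if (!is.finite(stance_end)) stance_end <- 60L
  structure(list(curve = rowMeans(curves), stance_end = as.integer(stance_end),
                 n_cycles = length(ic) - 1L),
            class = "cycle_curve")
}

#' Named peak angles from a cycle-normalized joint curve
#'
#' Extracts the configurable extrema set used as Step-2 predictors; the
#' angle at initial contact is the first curve sample (`Ang_IC`).
#'
#' @param curve A `cycle_curve` (or plain length-100 numeric vector).
#' @param joint Label prefixed to the output names (e.g. `"ankle"`).
#' @return Named numeric vector: `Ang_IC_<joint>`, `Ang_max_<joint>`,
#'   `Ang_min_<joint>`, `Ang_ROM_<joint>`.
#' @export
peak_angles <- function(curve, joint = "ankle") {
  v <- if (inherits(curve, "cycle_curve")) curve$curve else as.numeric(curve)
  if (length(v) != 100L) gs_param_error("expected a 100-point cycle curve")
  setNames(c(v[1L], max(v), min(v), max(v) - min(v)),
           paste0(c("Ang_IC_", "Ang_max_", "Ang_min_", "Ang_ROM_"), joint))
}

#' Read a multi-channel EMG / angle CSV
#'
#' Plain CSV with a `t` column and one column per channel, with a
#' `# fs=<Hz>` comment header.
#'
#' @param path File path.
#' @return List of channel vectors with attribute `fs`.
#' @export
read_channels_csv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("#\\s*fs=([0-9.eE+-]+)", first))[[1L]]
  if (length(m) < 2L) gs_param_error("missing '# fs=<Hz>' header line")
  d <- utils::read.csv(path, comment.char = "#")
  structure(as.list(d[setdiff(names(d), "t")]), fs = as.numeric(m[2L]))
}
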