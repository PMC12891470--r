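# Gait event detection and cycle segmentation from shank / trunk accelerometry.

#' Triaxial trunk acceleration signal
#'
#' Container for a lumbar (L3) triaxial accelerometer recording: anteroposterior
#' (AP), mediolateral (ML) and vertical (VT) series sampled at a common rate.
#'
#' @param ap,ml,vt Numeric vectors of equal length, acceleration in m/s^2.
#' @param fs Sampling rate in Hz (positive scalar).
#' @return An object of class `triaxial_signal`: a list with elements `ap`,
#'   `ml`, `vt` and `fs`.
#' @examples
#' sig <- triaxial_signal(sin(1:100 / 5), cos(1:100 / 5), sin(1:100 / 10), fs = 100)
#' @export
triaxial_signal <- function(ap, ml, vt, fs) {
  if (!is_scalar_num(fs) || fs <= 0) gs_param_error("fs must be a positive number")
  n <- length(ap)
  if (length(ml) != n || length(vt) != n)
    gs_param_error("ap, ml and vt must have equal length")
  if (!all(is.finite(ap), is.finite(ml), is.finite(vt)))
    gs_param_error("signal contains non-finite values")
  structure(list(ap = as.numeric(ap), ml = as.numeric(ml), vt = as.numeric(vt),
                 fs = fs), class = "triaxial_signal")
}

#' @export
print.triaxial_signal <- function(x, ...) {
  cat(sprintf("<triaxial_signal> %d samples @ %g Hz (%.2f s)\n",
              length(x$ap), x$fs, length(x$ap) / x$fs))
  invisible(x)
}

#' Gait events (initial contacts and toe-offs)
#'
#' @param ic_indices Integer sample indices of initial contacts, ascending.
#' @param to_indices Integer sample indices of toe-offs, ascending; each toe-off
#'   must fall between consecutive initial contacts.
#' @param fs Sampling rate in Hz.
#' @param meta Optional list of detection metadata (thresholds used, etc.).
#' @return An object of class `gait_events`.
#' @export
gait_events <- function(ic_indices, to_indices, fs, meta = list()) {
  ic <- as.integer(ic_indices); to <- as.integer(to_indices)
  if (length(ic) < 2L) gs_segmentation_error("need at least 2 initial contacts")
  if (is.unsorted(ic, strictly = TRUE) || (length(to) && is.unsorted(to, strictly = TRUE)))
    gs_param_error("event indices must be strictly increasing")
  for (t in to) {
    k <- findInterval(t, ic)
    if (k < 1L || k >= length(ic))
      gs_param_error("each toe-off must lie between consecutive initial contacts")
  }
  structure(list(ic_indices = ic, to_indices = to, fs = fs, meta = meta),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d ICs, %d TOs, %d cycles @ %g Hz\n",
              length(x$ic_indices), length(x$to_indices), n_cycles(x), x$fs))
  invisible(x)
}

#' Number of gait cycles defined by an event set
#' @param events A `gait_events` object.
#' @return Integer count of IC-to-IC cycles.
#' @export
n_cycles <- function(events) length(events$ic_indices) - 1L

#' Detect initial contact and toe-off from shank AP acceleration
#'
#' Initial contact (IC) is taken as a prominent positive peak of the
#' anteroposterior shank acceleration at the start of stance; toe-off (TO) as
#' the negative-to-positive zero crossing following the deepest trough between
#' consecutive ICs. The minimum peak distance is `0.5 / f_stride` (with the
#' stride frequency estimated from the dominant spectral peak) and the peak
#' prominence threshold is `0.5` times the robust (MAD-based) SD of the signal;
#' both are recorded in the returned metadata.
#'
#' @param shank_ap Numeric vector, shank AP acceleration (m/s^2).
#' @param fs Sampling rate in Hz (>= 50 recommended).
#' @return A [gait_events] object with detection parameters in `$meta`.
#' @export
detect_gait_events <- function(shank_ap, fs) {
  if (!is_scalar_num(fs) || fs <= 0) gs_param_error("fs must be positive")
  x <- as.numeric(shank_ap)
  n <- length(x)
  rsd <- stats::mad(x)
  if (!is.finite(rsd) || rsd == 0)
    gs_segmentation_error("signal has zero variance; no gait events detectable")

  # stride-frequency estimate: dominant peak of the demeaned spectrum in
  # the physiological band 0.3-3 Hz
  xd <- x - mean(x)
  spec <- Mod(fft(xd))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1) * fs / n
  band <- freqs >= 0.3 & freqs <= 3
  if (!any(band)) gs_segmentation_error("recording too short to estimate stride frequency")
  f_stride <- freqs[band][which.max(spec[band])]
  if (f_stride <= 0) f_stride <- 1

  min_dist <- max(1L, floor(0.5 / f_stride * fs))
  # prominence: at least 0.5 x robust SD, raised to half the extreme-tail
  # amplitude of the trace so broadband noise maxima are rejected on
  # impact-dominated (pulse-like) recordings
  tail_amp <- stats::quantile(x - mean(x), 0.995, names = FALSE)
  prom <- max(0.5 * rsd, 0.5 * tail_amp)

  # local maxima (boundary samples included) above threshold, then enforce
  # min distance keeping the larger peak of any conflicting pair
  interior <- c(FALSE, diff(sign(diff(x))) < 0, FALSE)
  interior[1L] <- x[1L] > x[2L]
  interior[n] <- x[n] > x[n - 1L]
  is_peak <- interior & (x > mean(x) + prom)
  cand <- which(is_peak)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  for (i in cand) {
    lo <- max(1L, i - min_dist); hi <- min(n, i + min_dist)
    if (!any(keep[lo:hi])) keep[i] <- TRUE
  }
  ic <- sort(which(keep))
  if (length(ic) < 2L)
    gs_segmentation_error("fewer than 2 initial contacts detected")

  # TO: deepest trough between consecutive ICs, then the next upward zero
  # crossing of the demeaned signal
  to <- integer(0)
  for (k in seq_len(length(ic) - 1L)) {
    seg <- ic[k]:ic[k + 1L]
    tr <- seg[which.min(x[seg])]
    z <- tr
    while (z < ic[k + 1L] && xd[z] < 0) z <- z + 1L
    if (z > ic[k] && z < ic[k + 1L]) to <- c(to, z)
  }
  gait_events(ic, to, fs,
              meta = list(stride_freq_estimate = f_stride,
                          min_peak_distance_samples = min_dist,
                          prominence_threshold = prom))
}

#' Drop transient strides at the start and end of a walk
#'
#' Removes the first `n_head` and last `n_tail` gait cycles (acceleration /
#' deceleration transients) from an event set, keeping the interior cycles.
#'
#' @param events A [gait_events] object.
#' @param n_head,n_tail Number of leading / trailing cycles to drop (default 3
#'   each, so a 16-cycle walk yields the 10 analysed cycles).
#' @return A [gait_events] object with `n_cycles(events) - n_head - n_tail`
#'   cycles.
#' @export
trim_transient_strides <- function(events, n_head = 3L, n_tail = 3L) {
  stopifnot(inherits(events, "gait_events"))
  nc <- n_cycles(events)
  if (nc - n_head - n_tail < 2L)
    gs_segmentation_error(sprintf(
      "trimming %d + %d cycles from a %d-cycle walk leaves fewer than 2 cycles",
      n_head, n_tail, nc))
  ic <- events$ic_indices[(1L + n_head):(length(events$ic_indices) - n_tail)]
  to <- events$to_indices[events$to_indices > ic[1L] &
                            events$to_indices < ic[length(ic)]]
  gait_events(ic, to, events$fs, meta = events$meta)
}

#' Extract a fixed number of consecutive gait cycles from a trunk signal
#'
#' Windows the triaxial signal over `n_cycles` consecutive cycles starting at
#' the first initial contact of (typically trimmed) events.
#'
#' @param signal A [triaxial_signal].
#' @param events A [gait_events] object (after transient trimming).
#' @param n_cycles Number of cycles to extract (default 10).
#' @return An object of class `stride_series`: list with `ap`, `ml`, `vt`
#'   windows, `fs`, per-cycle `boundaries` (sample indices relative to the
#'   window start), `stride_times` (s) and `mean_stride_time`.
#' @export
extract_cycles <- function(signal, events, n_cycles = 10L) {
  stopifnot(inherits(signal, "triaxial_signal"), inherits(events, "gait_events"))
  avail <- length(events$ic_indices) - 1L
  if (avail < n_cycles)
    gs_segmentation_error(sprintf("requested %d cycles but only %d available",
                                  n_cycles, avail))
  ic <- events$ic_indices[1:(n_cycles + 1L)]
  idx <- ic[1L]:(ic[n_cycles + 1L] - 1L)
  stride_times <- diff(ic) / events$fs
  structure(list(ap = signal$ap[idx], ml = signal$ml[idx], vt = signal$vt[idx],
                 fs = signal$fs,
                 boundaries = ic - ic[1L] + 1L,
                 stride_times = stride_times,
                 mean_stride_time = mean(stride_times)),
            class = "stride_series")
}

#' @export
print.stride_series <- function(x, ...) {
  cat(sprintf("<stride_series> %d cycles, %d samples, mean stride %.3f s\n",
              length(x$stride_times), length(x$ap), x$mean_stride_time))
  invisible(x)
}

#' Gait speed from a timed walkway traverse
#'
#' @param traverse_time_s Time to traverse the walkway, seconds (> 0).
#' @param distance_m Walkway length in metres (default 10).
#' @return Speed in m/s.
#' @examples
#' gait_speed(12.5)  # 0.8 m/s
#' @export
gait_speed <- function(traverse_time_s, distance_m = 10) {
  if (!is_scalar_num(traverse_time_s) || traverse_time_s <= 0)
    gs_param_error("traverse time must be positive")
  if (!is_scalar_num(distance_m) || distance_m <= 0)
    gs_param_error("distance must be positive")
  distance_m / traverse_time_s
}

#' Read / write signal and event CSV files
#'
#' Subject signals are stored as plain CSV with columns `t, ap, ml, vt` and a
#' first comment line `# fs=<Hz>`. Events are two-column CSV
#' (`event_type, sample_index`).
#'
#' @param path File path.
#' @param signal A [triaxial_signal] (for writing).
#' @param events A [gait_events] (for writing).
#' @return `read_signal_csv` returns a [triaxial_signal]; `read_events_csv` a
#'   [gait_events]; the writers return the path invisibly.
#' @name signal_io
NULL

#' @rdname signal_io
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "triaxial_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", signal$fs), con)
  t <- (seq_along(signal$ap) - 1) / signal$fs
  utils::write.table(data.frame(t = t, ap = signal$ap, ml = signal$ml, vt = signal$vt),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname signal_io
#' @export
read_signal_csv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("#\\s*fs=([0-9.eE+-]+)", first))[[1L]]
  if (length(m) < 2L) gs_param_error("missing '# fs=<Hz>' header line")
  fs <- as.numeric(m[2L])
  d <- utils::read.csv(path, comment.char = "#")
  triaxial_signal(d$ap, d$ml, d$vt, fs)
}

#' @rdname signal_io
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  d <- rbind(data.frame(event_type = "IC", sample_index = events$ic_indices),
             data.frame(event_type = "TO", sample_index = events$to_indices))
  utils::write.csv(d[order(d$sample_index), ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
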