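# Synthetic cohort generators.
#
# Two ground-truth paths are provided on purpose: the signal-level generator
# injects group structure through harmonic amplitudes, cycle jitter and noise
# (so the metric code is validated against signal-level ground truth), while
# the tabular generators inject standardized mean shifts directly on named
# features (so the selection / classification / regression layers have an
# exact oracle).

# evaluate expr under a temporary RNG state; global .Random.seed is restored
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic gait-stability cohort
#'
#' Collects every parameter of the synthetic cohort: group sizes (default
#' 71 stroke-like vs 39 control-like, the imbalance the analysis is designed
#' for), the standardized group difference injected on the discriminative
#' features, signal-generation parameters, and the three nonlinear structures
#' embedded in the even-to-uneven regression table (a 0.8 m/s speed
#' breakpoint, a U-shaped ankle-angle effect on SampEn_AP, and a harmonic-
#' ratio plateau at 1.5).
#'
#' @param n_pws,n_hc Group sizes (stroke-like / control-like), default 71/39.
#' @param seed Integer seed; every generator is a pure function of
#'   (spec, seed).
#' @param effect_size_d Standardized mean group difference injected on
#'   `RMS_VT`, `RMS_AP`, `RMS_ML`, `SampEn_AP` (up for PwS) and `HR_AP`
#'   (down for PwS); default 0.7, the middle of the d = 0.65-0.75 range
#'   reported for RMS metrics on uneven ground.
#' @param fs Accelerometer sampling rate in Hz (default 100).
#' @param stride_freq_mean Named vector, mean stride frequency (Hz) per group.
#' @param jitter Named vector, cycle-to-cycle stride-time jitter (relative SD)
#'   per group.
#' @param noise_sd Named list `group -> c(even=, uneven=)` additive
#'   acceleration noise SD (m/s^2).
#' @param speed_mean,speed_sd Named vectors, 10 m gait speed distribution
#'   (m/s) per group.
#' @param breakpoint_speed Even-surface speed (m/s) below which uneven-surface
#'   decline steepens (default 0.8).
#' @param hr_plateau Even-surface HR_AP above which the uneven-surface HR_AP
#'   saturates (default 1.5).
#' @param ushape_center Ankle dorsiflexion angle at initial contact (degrees)
#'   minimizing uneven-surface SampEn_AP (default 5).
#' @param reg_noise Multiplier on the regression-table noise SDs (1 =
#'   default realism, 0 = noiseless structural check).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pws = 71L, n_hc = 39L, seed = 1L,
                        effect_size_d = 0.7, fs = 100,
                        stride_freq_mean = c(PwS = 0.85, HC = 1.0),
                        jitter = c(PwS = 0.06, HC = 0.03),
                        noise_sd = list(PwS = c(even = 0.35, uneven = 0.5),
                                        HC = c(even = 0.2, uneven = 0.3)),
                        speed_mean = c(PwS = 0.75, HC = 1.2),
                        speed_sd = c(PwS = 0.2, HC = 0.15),
                        breakpoint_speed = 0.8, hr_plateau = 1.5,
                        ushape_center = 5, reg_noise = 1) {
  if (n_pws <= 0 || n_hc <= 0) gs_param_error("group sizes must be positive")
  if (!is_scalar_num(fs) || fs <= 0) gs_param_error("fs must be positive")
  if (!is_scalar_num(effect_size_d)) gs_param_error("effect_size_d must be finite")
  lo <- min(speed_mean - 3 * speed_sd); hi <- max(speed_mean + 3 * speed_sd)
  if (breakpoint_speed <= lo || breakpoint_speed >= hi)
    gs_param_error("breakpoint_speed outside the generated speed range")
  structure(list(n_pws = as.integer(n_pws), n_hc = as.integer(n_hc),
                 seed = as.integer(seed), effect_size_d = effect_size_d,
                 fs = fs, stride_freq_mean = stride_freq_mean, jitter = jitter,
                 noise_sd = noise_sd, speed_mean = speed_mean,
                 speed_sd = speed_sd, breakpoint_speed = breakpoint_speed,
                 hr_plateau = hr_plateau, ushape_center = ushape_center,
                 reg_noise = reg_noise),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d PwS / %d HC, d = %g, fs = %g Hz, seed = %d\n",
              x$n_pws, x$n_hc, x$effect_size_d, x$fs, x$seed))
  invisible(x)
}

# default harmonic content (amplitudes in m/s^2 at multiples of the stride
# frequency): AP/VT carry even harmonics (step-frequency dominant), ML odd
default_harmonics <- function() {
  list(ap = list(k = c(2, 4, 6), amp = c(0.8, 0.30, 0.10)),
       ml = list(k = c(1, 3, 5), amp = c(0.5, 0.20, 0.08)),
       vt = list(k = c(2, 4, 6), amp = c(1.0, 0.35, 0.15)))
}

#' Simulate a periodic triaxial trunk acceleration signal
#'
#' Builds a stride-phase-locked harmonic sum per axis: AP and VT energy at
#' even multiples of the stride frequency (the step frequency and its
#' overtones), ML at odd multiples, with per-stride duration jitter and
#' additive white noise. The programmed initial-contact times are returned as
#' ground truth for event-detection validation.
#'
#' @param stride_freq Mean stride frequency in Hz.
#' @param n_strides Number of strides (>= 16 so that trimming 3 + 3 leaves
#'   at least 10).
#' @param fs Sampling rate in Hz (>= 50).
#' @param jitter Relative SD of stride duration (0 = perfectly periodic).
#' @param noise_sd Additive white-noise SD (m/s^2).
#' @param harmonics Per-axis harmonic table as in `default_harmonics()`:
#'   lists `ap`, `ml`, `vt` each with integer multiples `k` and amplitudes
#'   `amp`.
#' @param phases Optional per-axis phase offsets (radians), defaults 0.
#' @param seed Integer seed (generator is deterministic given all arguments).
#' @return A [triaxial_signal] with attributes `ic_times`, `to_times` (s,
#'   toe-off programmed at 60 % of each stride) and `stride_times`.
#' @export
simulate_trunk_acceleration <- function(stride_freq, n_strides = 16L, fs = 100,
                                        jitter = 0.03, noise_sd = 0.2,
                                        harmonics = default_harmonics(),
                                        phases = c(ap = 0, ml = 0, vt = 0),
                                        seed = 1L) {
  if (!is_scalar_num(fs) || fs < 50) gs_param_error("fs must be >= 50 Hz")
  if (!is_scalar_num(stride_freq) || stride_freq <= 0)
    gs_param_error("stride_freq must be positive")
  if (n_strides < 16L) gs_param_error("need n_strides >= 16 (3+3 trim must leave >= 10)")
  with_seed(seed, {
    t0 <- 1 / stride_freq
    stride_times <- t0 * (1 + jitter * pmax(pmin(rnorm(n_strides), 2.5), -2.5))
    ic_times <- cumsum(c(0, stride_times))
    n <- floor(ic_times[n_strides + 1L] * fs)
    t <- (seq_len(n) - 1) / fs
    # stride phase: piecewise linear, 0 at each IC, 1 at the next
    phase <- stats::approx(ic_times, seq(0, n_strides), xout = t, rule = 2)$y
    mk_axis <- function(h, ph) {
      y <- numeric(n)
      for (i in seq_along(h$k))
        y <- y + h$amp[i] * sin(2 * pi * h$k[i] * phase + ph)
      y + rnorm(n, sd = noise_sd)
    }
    sig <- triaxial_signal(mk_axis(harmonics$ap, phases[["ap"]]),
                           mk_axis(harmonics$ml, phases[["ml"]]),
                           mk_axis(harmonics$vt, phases[["vt"]]), fs)
    attr(sig, "ic_times") <- ic_times
    attr(sig, "to_times") <- ic_times[-length(ic_times)] + 0.6 * stride_times
    attr(sig, "stride_times") <- stride_times
    sig
  })
}

#' Simulate a shank AP acceleration trace with programmed events
#'
#' Sharp positive pulses at each initial contact and negative troughs at each
#' toe-off, plus white noise — the waveform shape the IC/TO detector assumes.
#'
#' @param ic_times,to_times Event times in seconds (as returned by
#'   [simulate_trunk_acceleration()]).
#' @param fs Sampling rate (Hz).
#' @param duration_s Total duration (s); defaults to just past the last IC.
#' @param noise_sd Additive noise SD relative to the IC pulse amplitude 3.
#' @param seed Integer seed.
#' @return Numeric vector of shank AP acceleration.
#' @export
simulate_shank_ap <- function(ic_times, to_times, fs = 100,
                              duration_s = max(ic_times) + 0.2,
                              noise_sd = 0.15, seed = 1L) {
  with_seed(seed, {
    n <- floor(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    pulse <- function(centers, amp, width) {
      y <- numeric(n)
      for (c0 in centers) y <- y + amp * exp(-0.5 * ((t - c0) / width)^2)
      y
    }
    pulse(ic_times, 3, 0.025) + pulse(to_times, -2, 0.03) + rnorm(n, sd = noise_sd)
  })
}

# group-level signal parameters for one synthetic subject
subject_signal_params <- function(group, surface, spec) {
  list(stride_freq = spec$stride_freq_mean[[group]],
       jitter = spec$jitter[[group]],
       noise_sd = spec$noise_sd[[group]][[surface]])
}

#' Simulate a full subject record (signals, EMG, angles, timed walk)
#'
#' @param id Subject identifier.
#' @param group `"PwS"` or `"HC"`.
#' @param surface `"even"` or `"uneven"`.
#' @param spec A [cohort_spec].
#' @param seed Integer seed for this subject.
#' @param n_strides Strides to simulate (default 16).
#' @return A list of class `subject_record` with `trunk_signal` (a
#'   [triaxial_signal]), `shank_ap`, `emg` (5-channel list at 1000 Hz),
#'   `angles` (hip/knee/ankle at `fs`), and `gait_time_10m` (s).
#' @export
simulate_subject_record <- function(id, group = c("PwS", "HC"),
                                    surface = c("even", "uneven"),
                                    spec = cohort_spec(), seed = 1L,
                                    n_strides = 16L) {
  group <- match.arg(group); surface <- match.arg(surface)
  p <- subject_signal_params(group, surface, spec)
  trunk <- simulate_trunk_acceleration(p$stride_freq, n_strides, spec$fs,
                                       jitter = p$jitter, noise_sd = p$noise_sd,
                                       seed = seed)
  ic <- attr(trunk, "ic_times"); to <- attr(trunk, "to_times")
  shank <- simulate_shank_ap(ic, to, spec$fs, noise_sd = 0.15, seed = seed + 1L)
  with_seed(seed + 2L, {
    speed <- max(0.3, rnorm(1, spec$speed_mean[[group]], spec$speed_sd[[group]]))
    gait_time <- 10 / speed
    fs_emg <- 1000
    dur <- max(ic)
    t_emg <- seq(0, dur, by = 1 / fs_emg)
    phase <- stats::approx(ic, seq(0, length(ic) - 1L), xout = t_emg, rule = 2)$y %% 1
    burst <- function(lo, hi) as.numeric(phase >= lo & phase <= hi)
    env <- list(TA = burst(0, 0.12) + burst(0.85, 1), SOL = burst(0.1, 0.5),
                RF = burst(0, 0.2) + burst(0.55, 0.7), BF = burst(0.85, 1) + burst(0, 0.1),
                GM = burst(0, 0.3))
    emg <- lapply(env, function(e) (0.2 + e) * rnorm(length(e)))
    t_ang <- (seq_along(trunk$ap) - 1) / spec$fs
    phase_a <- stats::approx(ic, seq(0, length(ic) - 1L), xout = t_ang, rule = 2)$y %% 1
    angles <- list(
      hip = 25 * cos(2 * pi * phase_a) + rnorm(length(phase_a), sd = 0.5),
      knee = 30 * (0.2 + 0.8 * sin(pi * phase_a)^2) * (1 + 0.5 * (phase_a > 0.6)) +
        rnorm(length(phase_a), sd = 0.5),
      ankle = spec$ushape_center + rnorm(1, 0, 4) + 8 * sin(2 * pi * phase_a + 0.5) +
        rnorm(length(phase_a), sd = 0.3))
    structure(list(id = id, group = group, surface = surface,
                   trunk_signal = trunk, shank_ap = shank,
                   emg = emg, fs_emg = fs_emg, angles = angles,
                   gait_time_10m = gait_time, speed = speed),
              class = "subject_record")
  })
}

# baseline (HC, uneven-surface) feature distributions for the tabular path
feature_baselines <- function() {
  data.frame(
    feature = stability_feature_names(),
    mean = c(1.5, 1.2, 1.6,      # RMS AP/ML/VT
             1.8, 1.6, 2.0,      # HR
             0.22, 0.25, 0.20,   # SampEn
             8, 9, 7,            # RQA_rec
             92, 90, 94,         # RQA_det
             0.9, 1.0, 0.8),     # sLE
    sd = c(0.40, 0.35, 0.40,
           0.45, 0.40, 0.50,
           0.05, 0.06, 0.05,
           2.0, 2.2, 1.8,
           3.0, 3.5, 2.5,
           0.22, 0.25, 0.20))
}

# features carrying the injected group effect and its sign (PwS minus HC,
# in SD units per unit d)
effect_directions <- function() {
  c(RMS_VT = +1, RMS_AP = +1, RMS_ML = +1, SampEn_AP = +1, HR_AP = -1)
}

#' Simulate the imbalanced two-class feature cohort
#'
#' Draws the 18 uneven-surface stability features for `n_pws` stroke-like and
#' `n_hc` control-like subjects. Stroke-like rows receive mean shifts of
#' `+d x SD` on `RMS_VT`, `RMS_AP`, `RMS_ML`, `SampEn_AP` and `-d x SD` on
#' `HR_AP`; all other features are group-neutral noise. Demographic covariates
#' (age, height, weight, BMI) are drawn without any injected group difference.
#'
#' @param spec A [cohort_spec].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param with_signals If `TRUE`, also simulate per-subject signal records
#'   (slower; default `FALSE`).
#' @return A list with `features` (data.frame: `subject_id`, `group` factor
#'   with levels HC/PwS, 18 stability features, demographics), `truth` (the
#'   injected effect directions and d), and optionally `records`.
#' @export
simulate_classification_cohort <- function(spec = cohort_spec(),
                                           seed = spec$seed,
                                           with_signals = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- feature_baselines()
  eff <- effect_directions()
  n <- spec$n_pws + spec$n_hc
  group <- factor(rep(c("PwS", "HC"), c(spec$n_pws, spec$n_hc)),
                  levels = c("HC", "PwS"))
  feats <- with_seed(seed, {
    m <- sapply(seq_len(nrow(base)), function(j) {
      shift <- if (base$feature[j] %in% names(eff))
        eff[[base$feature[j]]] * spec$effect_size_d * base$sd[j] else 0
      rnorm(n, base$mean[j] + shift * (group == "PwS"), base$sd[j])
    })
    colnames(m) <- base$feature
    demo <- data.frame(
      age = rnorm(n, ifelse(group == "PwS", 63.8, 65.6), 7.4),
      height_cm = rnorm(n, 163, 8),
      weight_kg = rnorm(n, 61, 10))
    demo$bmi <- demo$weight_kg / (demo$height_cm / 100)^2
    cbind(data.frame(subject_id = sprintf("S%03d", seq_len(n)), group = group),
          as.data.frame(m), demo)
  })
  records <- NULL
  if (with_signals) {
    records <- lapply(seq_len(n), function(i)
      simulate_subject_record(feats$subject_id[i], as.character(group[i]),
                              "uneven", spec, seed = seed + 100L + i))
  }
  list(features = feats,
       truth = list(effect_features = names(eff), directions = eff,
                    d = spec$effect_size_d),
       records = records)
}

#' Simulate the even-to-uneven regression cohort
#'
#' Generates even-surface predictors (gait speed, ankle angle at initial
#' contact, HR_AP, RMS_VT, SampEn_AP, plus inert covariates) and
#' uneven-surface targets embedding three known structures:
#' \itemize{
#'   \item `uneven_speed`: continuous piecewise-linear in `even_speed`, with a
#'     steeper decline below `breakpoint_speed` (default 0.8 m/s);
#'   \item `uneven_RMS_VT`: elevated and flat below the breakpoint, declining
#'     above it;
#'   \item `uneven_SampEn_AP`: quadratic (U-shaped) in `Ang_IC_ankle` with
#'     minimum at `ushape_center`;
#'   \item `uneven_HR_AP`: linear ramp in even-surface `HR_AP` saturating once
#'     the even-surface value exceeds `hr_plateau` (default 1.5).
#' }
#' The generative parameters are returned as ground truth for recovery tests.
#'
#' @param spec A [cohort_spec].
#' @param n Number of subjects (default `n_pws + n_hc`).
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return List with `features` (data.frame of predictors + the four targets)
#'   and `truth` (breakpoint, U-center and quadratic coefficient, plateau
#'   location, slopes, noise SDs).
#' @export
simulate_regression_cohort <- function(spec = cohort_spec(),
                                       n = spec$n_pws + spec$n_hc,
                                       seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  bp <- spec$breakpoint_speed; uc <- spec$ushape_center; hp <- spec$hr_plateau
  ns <- spec$reg_noise * c(speed = 0.06, rms = 0.15, sampen = 0.035, hr = 0.08)
  truth <- list(breakpoint_speed = bp, speed_slope_above = 0.9,
                speed_extra_slope_below = 0.5, speed_intercept = -0.05,
                rms_drop_slope = 1.2, ushape_center = uc, quad_coef = 0.0035,
                hr_plateau = hp, hr_slope = 0.8, hr_intercept = 0.1,
                noise_sd = ns)
  feats <- with_seed(seed, {
    grp <- factor(rep(c("PwS", "HC"), c(spec$n_pws, spec$n_hc))[
      rep_len(seq_len(spec$n_pws + spec$n_hc), n)], levels = c("HC", "PwS"))
    even_speed <- pmin(pmax(rnorm(n, spec$speed_mean[as.character(grp)],
                                  spec$speed_sd[as.character(grp)]), 0.3), 1.7)
    ang <- rnorm(n, uc, 4.5)
    even_hr <- pmax(rnorm(n, 1.5, 0.45), 0.4)
    even_rms <- pmax(rnorm(n, 1.6, 0.4), 0.3)
    even_sampen <- pmax(rnorm(n, 0.22, 0.05), 0.05)
    ci_stance <- pmin(pmax(rnorm(n, 35, 8), 5), 90)
    age <- rnorm(n, 64.5, 7.4)
    uneven_speed <- truth$speed_intercept + truth$speed_slope_above * even_speed -
      truth$speed_extra_slope_below * pmax(bp - even_speed, 0) +
      rnorm(n, 0, ns[["speed"]])
    uneven_rms_vt <- 2.3 + 0.3 * even_rms -
      truth$rms_drop_slope * pmax(even_speed - bp, 0) + rnorm(n, 0, ns[["rms"]])
    uneven_sampen_ap <- 0.24 + 0.3 * even_sampen +
      truth$quad_coef * (ang - uc)^2 + rnorm(n, 0, ns[["sampen"]])
    uneven_hr_ap <- truth$hr_intercept + truth$hr_slope * pmin(even_hr, hp) +
      rnorm(n, 0, ns[["hr"]])
    data.frame(subject_id = sprintf("R%03d", seq_len(n)), group = grp,
               even_speed = even_speed, Ang_IC_ankle = ang,
               even_HR_AP = even_hr, even_RMS_VT = even_rms,
               even_SampEn_AP = even_sampen, CI_TA_SOL_stance = ci_stance,
               age = age,
               uneven_speed = uneven_speed, uneven_RMS_VT = uneven_rms_vt,
               uneven_SampEn_AP = uneven_sampen_ap, uneven_HR_AP = uneven_hr_ap)
  })
  list(features = feats, truth = truth)
}

#' Read / write feature tables and cohort specs
#'
#' Feature tables are plain CSV with a header row; specs are YAML.
#'
#' @param table A data.frame feature table.
#' @param spec A [cohort_spec].
#' @param path File path.
#' @return Readers return the parsed object; writers the path, invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_feature_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("group" %in% names(d)) d$group <- factor(d$group, levels = c("HC", "PwS"))
  d
}

#' @rdname cohort_io
#' @export
write_spec_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_spec_yaml <- function(path) {
  do.call(cohort_spec, yaml::read_yaml(path))
}
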