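test_that("cohort spec validates its parameters", {
  expect_error(cohort_spec(n_pws = 0), class = "gaitstab_param_error")
  expect_error(cohort_spec(fs = -10), class = "gaitstab_param_error")
  expect_error(cohort_spec(breakpoint_speed = 9), class = "gaitstab_param_error")
  sp <- cohort_spec()
  expect_equal(c(sp$n_pws, sp$n_hc), c(71L, 39L))
  expect_equal(sp$effect_size_d, 0.7)
  expect_equal(sp$breakpoint_speed, 0.8)
  expect_equal(sp$hr_plateau, 1.5)
})

test_that("signal generator is a pure function of its arguments and seed", {
  a <- simulate_trunk_acceleration(1, 16, 100, seed = 33)
  b <- simulate_trunk_acceleration(1, 16, 100, seed = 33)
  expect_identical(a, b)
  c <- simulate_trunk_acceleration(1, 16, 100, seed = 34)
  expect_false(identical(a$ap, c$ap))
  expect_error(simulate_trunk_acceleration(1, 10, 100),
               class = "gaitstab_param_error")
  expect_error(simulate_trunk_acceleration(-1, 16, 100),
               class = "gaitstab_param_error")
})

test_that("noise-free generation yields near-perfect downstream periodicity", {
  sig <- simulate_trunk_acceleration(1, 16, 100, jitter = 0, noise_sd = 0,
                                     seed = 1)
  ic <- round(attr(sig, "ic_times") * 100) + 1L
  st <- extract_cycles(sig, trim_transient_strides(
    gait_events(ic, integer(0), 100)), 10)
  hr <- compute_stability_features(st, 1)$HR_AP
  expect_gt(hr, 10)
})

test_that("doubling the noise raises the raw RMS in every seeded replicate", {
  for (s in 1:20) {
    lo <- simulate_trunk_acceleration(1, 16, 100, jitter = 0.03,
                                      noise_sd = 0.2, seed = s)
    hi <- simulate_trunk_acceleration(1, 16, 100, jitter = 0.03,
                                      noise_sd = 0.4, seed = s)
    expect_gt(sqrt(mean((hi$vt - mean(hi$vt))^2)),
              sqrt(mean((lo$vt - mean(lo$vt))^2)))
  }
})

test_that("classification cohort has exact group counts and injected effects", {
  coh <- simulate_classification_cohort(cohort_spec(), seed = 4)
  expect_equal(as.vector(table(coh$features$group)), c(39L, 71L))
  expect_identical(coh$features, simulate_classification_cohort(
    cohort_spec(), seed = 4)$features)
  expect_setequal(coh$truth$effect_features,
                  c("RMS_VT", "RMS_AP", "RMS_ML", "SampEn_AP", "HR_AP"))
  # empirical effect size lands in the sampling band around d = 0.7 for most
  # draws (the band is ~ +/- 1.5 standard errors wide)
  ds <- vapply(1:10, function(s) {
    f <- simulate_classification_cohort(cohort_spec(), seed = s)$features
    x <- split(f$RMS_VT, f$group)
    (mean(x$PwS) - mean(x$HC)) / sqrt((var(x$PwS) + var(x$HC)) / 2)
  }, numeric(1))
  expect_gte(sum(ds >= 0.4 & ds <= 1.0), 7)
  expect_gt(mean(ds), 0.45)
  expect_lt(mean(ds), 0.9)
})

test_that("null cohorts are calibrated and d = 0.7 gives the designed power", {
  # type-I side: d = 0 should leave the Welch test non-significant
  null_rej <- 0L
  for (s in 1:60) {
    f <- simulate_classification_cohort(cohort_spec(effect_size_d = 0),
                                        seed = s)$features
    pv <- t.test(RMS_VT ~ group, data = f)$p.value
    null_rej <- null_rej + (pv < 0.05)
  }
  expect_gte((60 - null_rej) / 60, 0.9)
  # power side: d = 0.7 at 71/39 rejects in at least 80 % of replicates
  rej <- 0L
  for (s in 1:200) {
    f <- simulate_classification_cohort(cohort_spec(), seed = 1000 + s)$features
    rej <- rej + (t.test(RMS_VT ~ group, data = f)$p.value < 0.05)
  }
  expect_gte(rej / 200, 0.8)
})

test_that("regression cohort embeds its three structures continuously", {
  spec0 <- cohort_spec(reg_noise = 0)
  reg <- simulate_regression_cohort(spec0, n = 400, seed = 2)
  tr <- reg$truth
  # continuity at the breakpoint: predicted values from the generative form
  f_speed <- function(v) tr$speed_intercept + tr$speed_slope_above * v -
    tr$speed_extra_slope_below * pmax(tr$breakpoint_speed - v, 0)
  eps <- 1e-9
  expect_equal(f_speed(0.8 - eps), f_speed(0.8 + eps), tolerance = 1e-6)
  # plateau: identical uneven HR for even HR 1.6 and 2.0 once saturated
  d <- reg$features
  hr_at <- function(h) tr$hr_intercept + tr$hr_slope * pmin(h, tr$hr_plateau)
  expect_identical(hr_at(1.6), hr_at(2.0))
  # noiseless columns reproduce the generative forms exactly
  expect_equal(d$uneven_speed, f_speed(d$even_speed), tolerance = 1e-12)
  expect_equal(d$uneven_HR_AP, hr_at(d$even_HR_AP), tolerance = 1e-12)
})

test_that("the embedded breakpoint is recoverable by least-squares changepoint search", {
  reg <- simulate_regression_cohort(cohort_spec(), n = 200, seed = 1)
  bp <- locate_breakpoint(reg$features$even_speed, reg$features$uneven_speed)
  expect_lt(abs(as.numeric(bp) - 0.8), 0.1)
  # plateau and U-shape recoverable from the raw table too
  pl <- locate_plateau(reg$features$even_HR_AP, reg$features$uneven_HR_AP)
  expect_lt(abs(as.numeric(pl) - 1.5), 0.15)
  us <- fit_ushape(reg$features$Ang_IC_ankle, reg$features$uneven_SampEn_AP)
  expect_gt(us$quad_coef, 0)
  expect_lt(abs(us$vertex - 5), 2)
})

test_that("subject records carry consistent multimodal channels", {
  rec <- simulate_subject_record("S1", "PwS", "uneven", cohort_spec(), seed = 6)
  expect_s3_class(rec$trunk_signal, "triaxial_signal")
  expect_named(rec$emg, c("TA", "SOL", "RF", "BF", "GM"))
  expect_named(rec$angles, c("hip", "knee", "ankle"))
  expect_gt(rec$gait_time_10m, 0)
  expect_identical(rec$trunk_signal$ap,
                   simulate_subject_record("S1", "PwS", "uneven", cohort_spec(),
                                           seed = 6)$trunk_signal$ap)
})

test_that("feature tables and specs round-trip through CSV / YAML", {
  coh <- simulate_classification_cohort(cohort_spec(n_pws = 6, n_hc = 4), seed = 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(coh$features, p)
  back <- read_feature_csv(p)
  expect_equal(levels(back$group), c("HC", "PwS"))
  expect_equal(back$RMS_VT, coh$features$RMS_VT, tolerance = 1e-9)
  sp <- cohort_spec(n_pws = 10, n_hc = 5, effect_size_d = 0.3)
  py <- withr::local_tempfile(fileext = ".yaml")
  write_spec_yaml(sp, py)
  expect_equal(read_spec_yaml(py)$effect_size_d, 0.3)
})
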