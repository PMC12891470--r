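test_that("speed-normalized RMS follows its closed form", {
  expect_equal(rms_normalized(rep(3.7, 500), 1.1), 0)
  t <- seq(0, 10, by = 0.01)
  A <- 2.5
  x <- A * sin(2 * pi * 2 * t)
  expect_equal(rms_normalized(x, 1), A / sqrt(2), tolerance = 1e-3)
  expect_equal(rms_normalized(x, 2), rms_normalized(x, 1) / 4)
  # offset invariance and linear amplitude scaling
  expect_equal(rms_normalized(x + 5, 1), rms_normalized(x, 1))
  expect_equal(rms_normalized(3 * x, 1), 3 * rms_normalized(x, 1))
  expect_error(rms_normalized(x, 0), class = "gaitstab_param_error")
})

test_that("harmonic ratio separates even- and odd-harmonic energy", {
  fs <- 100; f0 <- 1
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)     # exactly 10 strides
  step <- sin(2 * pi * 2 * f0 * t)          # pure step-frequency component
  expect_gt(harmonic_ratio(step, f0, fs, "AP"), 100)
  stride <- sin(2 * pi * f0 * t)            # pure stride-frequency component
  expect_lt(harmonic_ratio(stride, f0, fs, "AP"), 0.01)
  # ML convention is inverted
  expect_gt(harmonic_ratio(stride, f0, fs, "ML"), 100)
  # equal-amplitude harmonics 1..20 give HR = 1 on any axis
  eq <- rowSums(sapply(1:20, function(k) sin(2 * pi * k * f0 * t + k)))
  for (ax in c("AP", "ML", "VT"))
    expect_equal(harmonic_ratio(eq, f0, fs, ax), 1.0, tolerance = 1e-6)
  # amplitude-scaling invariance
  mix <- sin(2 * pi * 2 * f0 * t) + 0.3 * sin(2 * pi * 3 * f0 * t)
  expect_equal(harmonic_ratio(5 * mix, f0, fs, "AP"),
               harmonic_ratio(mix, f0, fs, "AP"), tolerance = 1e-9)
})

test_that("sample entropy matches the brute-force oracle exactly", {
  x_small <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3)
  r_abs <- 0.5
  oracle <- sampen_oracle(x_small, 2L, r_abs)
  got <- sample_entropy(x_small, m = 2L, r_factor = r_abs / sd(x_small))
  expect_identical(as.numeric(got), oracle$sampen)
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(80 + 20 * i)
    r <- 0.2 * sd(x)
    expect_identical(as.numeric(sample_entropy(x, 2L, 0.2)),
                     sampen_oracle(x, 2L, r)$sampen)
  }
  # m = 3 path
  x <- rnorm(150)
  expect_identical(as.numeric(sample_entropy(x, 3L, 0.3)),
                   sampen_oracle(x, 3L, 0.3 * sd(x))$sampen)
})

test_that("sample entropy behaves at its limits", {
  expect_equal(as.numeric(sample_entropy(rep(2, 300))), 0)
  # periodic windows are more regular than their shuffles
  t <- seq(0, 10, by = 0.01)
  wins <- 0L
  set.seed(11)
  for (i in 1:20) {
    x <- sin(2 * pi * t) + rnorm(length(t), sd = 0.05)
    wins <- wins + (as.numeric(sample_entropy(x)) <
                      as.numeric(sample_entropy(sample(x))))
  }
  expect_gte(wins, 19)
})

test_that("recurrence quantification matches the brute-force oracle exactly", {
  cfg <- metric_config(rqa_dim = 3L, rqa_delay = 4L)
  set.seed(7)
  for (i in 1:3) {
    x <- sin(seq(0, 8 * pi, length.out = 150)) + rnorm(150, sd = 0.3)
    got <- rqa(x, cfg)
    want <- rqa_oracle(x, 3L, 4L, cfg$rqa_radius_factor * sd(x) * sqrt(3), 2L, 4L)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("recurrence metrics read periodicity correctly", {
  expect_equal(rqa(rep(1.3, 200)), c(rec = 100, det = 100))
  t <- seq(0, 20 * pi, length.out = 1000)
  clean <- rqa(sin(t))
  expect_gte(clean[["det"]], 95)
  set.seed(3)
  noise <- rqa(rnorm(1000))
  expect_lt(noise[["det"]], clean[["det"]])
  expect_error(rqa(rnorm(30), metric_config(rqa_dim = 10L, rqa_delay = 10L)),
               class = "gaitstab_param_error")
})

test_that("short-term Lyapunov exponent is flat for periodic and grows with noise", {
  sig <- simulate_trunk_acceleration(1, 16, 100, jitter = 0, noise_sd = 0, seed = 5)
  ic <- round(attr(sig, "ic_times") * 100) + 1L
  ev <- trim_transient_strides(gait_events(ic, integer(0), 100))
  st <- extract_cycles(sig, ev, 10)
  sle0 <- short_term_lyapunov(st$ap, st$boundaries)
  expect_lte(abs(as.numeric(sle0)), 0.05)
  sign <- simulate_trunk_acceleration(1, 16, 100, jitter = 0, noise_sd = 0.1, seed = 5)
  stn <- extract_cycles(sign, ev, 10)
  sle_n <- short_term_lyapunov(stn$ap, stn$boundaries)
  expect_gt(as.numeric(sle_n), as.numeric(sle0))
})

test_that("full feature computation is deterministic and scales with speed", {
  sig <- simulate_trunk_acceleration(1, 16, 100, jitter = 0.03, noise_sd = 0.2,
                                     seed = 8)
  ic <- round(attr(sig, "ic_times") * 100) + 1L
  ev <- trim_transient_strides(gait_events(ic, integer(0), 100))
  st <- extract_cycles(sig, ev, 10)
  f1 <- compute_stability_features(st, 1.0)
  f2 <- compute_stability_features(st, 1.0)
  expect_identical(f1, f2)
  expect_named(f1, stability_feature_names(), ignore.order = TRUE)
  f08 <- compute_stability_features(st, 0.8)
  for (ax in c("AP", "ML", "VT")) {
    expect_equal(f08[[paste0("RMS_", ax)]],
                 f1[[paste0("RMS_", ax)]] / 0.64, tolerance = 1e-12)
    # speed normalization must not touch the other metrics
    expect_identical(f08[[paste0("SampEn_", ax)]], f1[[paste0("SampEn_", ax)]])
  }
})

test_that("control-like subjects show lower RMS_VT and higher HR_AP than stroke-like", {
  spec <- cohort_spec()
  hits_rms <- 0L; hits_hr <- 0L
  n_seeds <- 12L
  feats_of <- function(rec) {
    ev <- trim_transient_strides(detect_gait_events(rec$shank_ap, spec$fs))
    st <- extract_cycles(rec$trunk_signal, ev, 10)
    compute_stability_features(st, rec$speed)
  }
  for (s in seq_len(n_seeds)) {
    fh <- feats_of(simulate_subject_record("h", "HC", "uneven", spec, seed = s * 7))
    fp <- feats_of(simulate_subject_record("p", "PwS", "uneven", spec, seed = s * 7 + 3))
    hits_rms <- hits_rms + (fh$RMS_VT < fp$RMS_VT)
    hits_hr <- hits_hr + (fh$HR_AP > fp$HR_AP)
  }
  expect_gte(hits_rms / n_seeds, 0.9)
  expect_gte(hits_hr / n_seeds, 0.9)
})
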