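test_that("signal and event containers enforce their invariants", {
  expect_error(triaxial_signal(1:10, 1:9, 1:10, 100), class = "gaitstab_param_error")
  expect_error(triaxial_signal(1:10, 1:10, 1:10, -1), class = "gaitstab_param_error")
  expect_error(gait_events(c(10L), integer(0), 100), class = "gaitstab_segmentation_error")
  expect_error(gait_events(c(10L, 5L, 60L), integer(0), 100),
               class = "gaitstab_param_error")
  # TO outside its IC interval
  expect_error(gait_events(c(10L, 110L), 150L, 100), class = "gaitstab_param_error")
  ev <- gait_events(c(10L, 110L, 210L), c(70L, 170L), 100)
  expect_equal(n_cycles(ev), 2L)
})

test_that("events are detected at programmed contact times within 30 ms", {
  for (s in 1:10) {
    sig <- simulate_trunk_acceleration(1.0, n_strides = 16, fs = 100,
                                       jitter = 0.03, noise_sd = 0.2, seed = s)
    shank <- simulate_shank_ap(attr(sig, "ic_times"), attr(sig, "to_times"),
                               fs = 100, seed = s + 500)
    ev <- detect_gait_events(shank, 100)
    true_ic <- round(attr(sig, "ic_times") * 100) + 1
    offsets <- vapply(true_ic, function(t) min(abs(ev$ic_indices - t)), numeric(1))
    expect_true(all(offsets <= 3))                 # 30 ms at 100 Hz
    expect_equal(length(ev$ic_indices), length(true_ic))
    # TOs fall between consecutive ICs by construction
    expect_true(all(diff(ev$ic_indices) > 0))
  }
})

test_that("event detection records its thresholds and rejects degenerate input", {
  sig <- simulate_trunk_acceleration(1.0, 16, 100, seed = 2)
  shank <- simulate_shank_ap(attr(sig, "ic_times"), attr(sig, "to_times"),
                             fs = 100, seed = 3)
  ev <- detect_gait_events(shank, 100)
  expect_true(all(c("stride_freq_estimate", "min_peak_distance_samples",
                    "prominence_threshold") %in% names(ev$meta)))
  expect_error(detect_gait_events(rep(1, 1000), 100),
               class = "gaitstab_segmentation_error")
  # orientation sensitivity: reversed signal must not crash, events differ
  rev_ev <- tryCatch(detect_gait_events(rev(shank), 100), condition = function(c) NULL)
  if (!is.null(rev_ev)) expect_false(identical(rev_ev$ic_indices, ev$ic_indices))
})

test_that("transient-stride trimming removes exactly head and tail cycles", {
  ic <- as.integer(seq(1, 1601, by = 100))      # 16 cycles
  ev <- gait_events(ic, integer(0), 100)
  tr <- trim_transient_strides(ev)
  expect_equal(n_cycles(tr), 10L)
  expect_equal(tr$ic_indices, ic[4:14])
  expect_identical(trim_transient_strides(ev, 0L, 0L)$ic_indices, ic)
  ev7 <- gait_events(ic[1:8], integer(0), 100)  # 7 cycles
  expect_error(trim_transient_strides(ev7), class = "gaitstab_segmentation_error")
  # trim composition: trim(1,1) twice == trim(2,2)
  expect_equal(trim_transient_strides(trim_transient_strides(ev, 1L, 1L), 1L, 1L),
               trim_transient_strides(ev, 2L, 2L))
})

test_that("cycle extraction spans the requested window exactly", {
  sig <- simulate_trunk_acceleration(1 / 1.1, n_strides = 16, fs = 100,
                                     jitter = 0, noise_sd = 0, seed = 1)
  ic <- round(attr(sig, "ic_times") * 100) + 1L
  ev <- trim_transient_strides(gait_events(ic, integer(0), 100))
  st <- extract_cycles(sig, ev, n_cycles = 10)
  expect_true(abs(length(st$ap) - 1100) <= 1)   # 10 x 1.1 s at 100 Hz
  expect_equal(length(st$stride_times), 10L)
  expect_true(all(st$stride_times > 0))
  one <- extract_cycles(sig, ev, n_cycles = 1)
  expect_equal(length(one$ap), diff(ev$ic_indices[1:2]))
  expect_error(extract_cycles(sig, ev, n_cycles = 11),
               class = "gaitstab_segmentation_error")
})

test_that("gait speed is distance over time with guarded input", {
  expect_equal(gait_speed(12.5), 0.8)
  expect_equal(gait_speed(10), 1.0)
  expect_error(gait_speed(0), class = "gaitstab_param_error")
})

test_that("signal CSV round-trips preserve samples and sampling rate", {
  sig <- simulate_trunk_acceleration(1, 16, 100, seed = 9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, p)
  back <- read_signal_csv(p)
  expect_equal(back$fs, 100)
  expect_equal(back$ap, sig$ap, tolerance = 1e-12)
  ev <- gait_events(c(10L, 110L, 210L), c(70L, 170L), 100)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev, p2)
  d <- read.csv(p2)
  expect_equal(sort(d$sample_index[d$event_type == "IC"]), c(10L, 110L, 210L))
})
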