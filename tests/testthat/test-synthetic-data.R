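hs <- function(...) {
  utils::modifyList(list(mean_ibi_ms = 800, sdnn_ms = 50, lf_hf_ratio = 2), list(...))
}

test_that("beat generation hits the configured mean rate and variability limits", {
  b <- generate_beat_times(hs(), 180, seed = 5)
  expect_gte(length(b), 200)           # 180 s / 0.8 s with modulation slack
  expect_lte(length(b), 250)
  expect_lt(abs(mean(diff(b)) * 1000 - 800) / 800, 0.02)

  # zero-variability limit: perfectly periodic beats
  b0 <- generate_beat_times(hs(sdnn_ms = 0), 120, seed = 5)
  expect_lt(sd(diff(b0)) * 1000, 1e-6)
  expect_equal(mean(diff(b0)) * 1000, 800, tolerance = 1e-6)

  expect_error(generate_beat_times(hs(sdnn_ms = 400), 120, seed = 1),
               "infeasible")
  expect_error(generate_beat_times(hs(), 30, seed = 1))
})

test_that("generation is deterministic under a fixed seed", {
  expect_identical(generate_beat_times(hs(), 120, seed = 9),
                   generate_beat_times(hs(), 120, seed = 9))
  cfg <- motion_free_config(n_subjects = 2, seed = 3,
                            schedule = short_schedule())
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1[[1]]$device$bvp$values, c2[[1]]$device$bvp$values)
  expect_identical(c1[[2]]$truth$beat_times, c2[[2]]$truth$beat_times)
})

test_that("synthetic ECG carries one sharp deflection per beat", {
  beats <- c(1, 2.1, 3.4)
  ecg <- synth_ecg(beats, noise_sd = 0, duration_s = 5, seed = 1)
  pk <- naive_ecg_peaks(ecg)
  expect_length(pk, 3)
  expect_lt(max(abs(pk - beats)) * 1000, 10)

  # round trip against a realistic beat train
  b <- generate_beat_times(hs(), 120, seed = 4)
  ecg2 <- synth_ecg(b, noise_sd = 0.02, duration_s = 120, seed = 2)
  pk2 <- naive_ecg_peaks(ecg2)
  expect_length(pk2, length(b))
  expect_lt(max(abs(pk2 - b)) * 1000, 10)

  flat <- synth_ecg(numeric(0), noise_sd = 0.02, duration_s = 5, seed = 3)
  expect_lt(max(abs(flat$values)), 5 * 0.02 * 1.5)
  expect_error(synth_ecg(beats, noise_sd = 0.5), "noise_sd")
})

test_that("motion-free BVP yields no artifact intervals and recoverable beats", {
  sched <- short_schedule()
  b <- generate_beat_times(hs(), 480, seed = 6)
  b <- b[b < 479.5]
  out <- synth_bvp_accel(b, synth_config(motion_spec = no_motion())$motion_spec,
                         sched, seed = 8)
  expect_equal(nrow(out$artifact_intervals), 0)
  ibi <- reconstruct_bvp_ibi(out$bvp, filter_spec(0.5, 3))
  expect_equal(length(attr(ibi, "beat_times_all")), length(b))
})

test_that("BVP corruption is linear in the burst amplitude", {
  sched <- short_schedule()
  b <- generate_beat_times(hs(), 470, seed = 6)
  ms <- synth_config()$motion_spec
  ms$burst_rate_per_min[] <- 2
  noise0 <- list(bvp_sd = 0, accel_sd_g = 0)
  bvp_at <- function(amp) {
    ms$burst_amplitude_g <- amp
    synth_bvp_accel(b, ms, sched, seed = 21, noise_spec = noise0)
  }
  r0 <- bvp_at(0); r1 <- bvp_at(0.3); r2 <- bvp_at(0.6)
  expect_identical(r1$artifact_intervals, r2$artifact_intervals)
  c1 <- r1$bvp$values - r0$bvp$values
  c2 <- r2$bvp$values - r0$bvp$values
  expect_gt(sqrt(mean(c1^2)), 0)
  expect_equal(sqrt(mean(c2^2)) / sqrt(mean(c1^2)), 2, tolerance = 1e-6)
})

test_that("the native IBI stream drops exactly the beats inside bursts", {
  b <- seq(0.8, 100, by = 0.8)
  full <- synth_native_ibi(b, data.frame(start_s = numeric(0),
                                         stop_s = numeric(0)))
  expect_equal(length(full), length(b) - 1)
  expect_equal(attr(full, "fraction_retained"), 1)

  gone <- synth_native_ibi(b, data.frame(start_s = 0, stop_s = 100))
  expect_length(gone, 0)

  # intervals covering ~50% of the span retain ~50% of the entries
  iv <- data.frame(start_s = seq(0, 90, by = 10),
                   stop_s = seq(5, 95, by = 10))
  half <- synth_native_ibi(b, iv)
  expect_equal(attr(half, "fraction_retained"), 0.5, tolerance = 0.1)

  # retained entries keep their true intervals, so dropped predecessors
  # are visible as gaps
  expect_true(all(abs(half$intervals - 800) < 1e-9))
})

test_that("synthetic EDA matches its analytic construction", {
  sched <- condition_schedule("Baseline", 0, 300)
  spec <- synth_config()$eda_spec
  spec$drift_uS_per_min <- 0
  spec$artifact_steps_wrist <- 0
  spec$artifact_steps_gold <- 0

  # no SCRs, no drift, no noise, no artifacts: constant series
  spec0 <- spec
  spec0$scr_rate_per_min[] <- 0
  e0 <- synth_eda(spec0, sched, site = "wrist", seed = 2, noise_sd = 0)
  expect_equal(diff(range(e0$eda$values)), 0)

  # quadrature: integral above baseline = kernel area x summed amplitudes
  e <- synth_eda(spec, sched, site = "finger", seed = 7, noise_sd = 0)
  area <- sum(e$eda$values - spec$tonic_base_uS) / e$eda$fs
  kern_area <- integrate(scr_kernel, 0, 30)$value
  expect_equal(area, kern_area * sum(e$truth$scr_amplitudes),
               tolerance = 0.02)

  # wrist attenuation halves the SCR peaks for the same seed
  w <- synth_eda(spec, sched, site = "wrist", seed = 7, noise_sd = 0)
  expect_equal(w$truth$scr_times, e$truth$scr_times)
  expect_equal(max(w$eda$values - spec$tonic_base_uS) /
                 max(e$eda$values - spec$tonic_base_uS),
               spec$wrist_attenuation, tolerance = 0.05)
  expect_equal(w$eda$fs, 4)
  expect_equal(e$eda$fs, 500)
})
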