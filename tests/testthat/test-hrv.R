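test_that("R-peak detection recovers clean synthetic beats exactly", {
  beats <- seq(1, 119, by = 1)  # exactly 1 Hz
  ecg <- synth_ecg(beats, noise_sd = 0.02, duration_s = 120, seed = 3)
  ibi <- detect_r_peaks(ecg)
  expect_length(attr(ibi, "beat_times_all"), length(beats))
  expect_true(all(abs(ibi$intervals - 1000) < 10))

  hs <- list(mean_ibi_ms = 800, sdnn_ms = 50, lf_hf_ratio = 2)
  b <- generate_beat_times(hs, 180, seed = 12)
  ecg2 <- synth_ecg(b, noise_sd = 0.02, seed = 4)  # runs 1 s past the last beat
  ibi2 <- detect_r_peaks(ecg2)
  bt <- attr(ibi2, "beat_times_all")
  expect_length(bt, length(b))                     # no misses, no extras
  expect_lt(max(abs(bt - b)) * 1000, 10)

  flat <- uniform_series(rep(0, 500 * 30), fs = 500)
  expect_length(detect_r_peaks(flat), 0)
  expect_error(detect_r_peaks(uniform_series(rnorm(100), fs = 100)), "200")
  expect_error(detect_r_peaks(uniform_series(rnorm(300), fs = 500)), "warm-up")
})

test_that("artifact-free segment mining respects contiguity and the run floor", {
  # fully contiguous 50-interval stream: one run spanning all beats
  b <- seq(0, 40, by = 0.8)
  ib <- ibi_from_beats(b)
  seg <- find_artifact_free_segments(ib, min_run = 10)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_intervals, length(b) - 1)
  expect_equal(seg$start_s, 0)
  expect_equal(seg$stop_s, max(b))

  # 9 contiguous intervals: below the floor
  expect_equal(nrow(find_artifact_free_segments(
    ibi_from_beats(seq(0, 7.2, by = 0.8)), min_run = 10)), 0)

  # one mid-gap: two runs, kept iff each >= 10 intervals
  beats <- c(seq(0, 12, by = 0.8), seq(14, 30, by = 0.8))
  native <- synth_native_ibi(beats, data.frame(start_s = 12.5, stop_s = 13.5))
  segs <- find_artifact_free_segments(native, min_run = 10)
  # enumeration oracle: count contiguous entries directly
  gaps <- abs(diff(native$beat_times) * 1000 - native$intervals[-1]) > 1
  runs <- rle(c(TRUE, !gaps))  # membership of each entry in the current run
  lens <- tapply(seq_along(native$beat_times),
                 cumsum(c(1, gaps)), length)
  expect_equal(nrow(segs), sum(lens >= 10))
})

test_that("PSD subtraction finds the cardiac fundamental", {
  fs <- 64
  t <- (0:(180 * fs - 1)) / fs
  bvp <- uniform_series(sin(2 * pi * 1.2 * t), fs)
  mag <- uniform_series(rnorm(180 * 32, sd = 1e-4), 32)
  segs <- data.frame(start_s = 0, stop_s = 180)
  spec <- subject_band_from_psd_subtraction(bvp, mag, segs)
  expect_equal(spec$low_cut, 1.1, tolerance = 0.02)
  expect_equal(spec$high_cut, 1.3, tolerance = 0.02)

  # out-of-range fundamental: fallback band with a warning
  slow <- uniform_series(sin(2 * pi * 0.4 * t), fs)
  expect_warning(
    sp <- subject_band_from_psd_subtraction(slow, mag, segs),
    "fall"
  )
  expect_equal(c(sp$low_cut, sp$high_cut), c(0.5, 3))
  expect_true(attr(sp, "fallback"))

  # dominant motion tone is cancelled by the subtraction
  bvp2 <- uniform_series(3 * sin(2 * pi * 1.0 * t) + sin(2 * pi * 1.3 * t), fs)
  t32 <- (0:(180 * 32 - 1)) / 32
  mag2 <- uniform_series(3 * sin(2 * pi * 1.0 * t32), 32)
  sp2 <- subject_band_from_psd_subtraction(bvp2, mag2, segs)
  expect_equal(attr(sp2, "fundamentals"),
               rep(1.3, length(attr(sp2, "fundamentals"))), tolerance = 0.02)
  expect_error(subject_band_from_psd_subtraction(bvp, mag, segs[0, ]))
})

test_that("BVP reconstruction recovers ground-truth beats on clean data", {
  cfg <- motion_free_config(schedule = short_schedule())
  sub <- simulate_subject(cfg, 31)
  ibi <- reconstruct_bvp_ibi(sub$device$bvp, filter_spec(0.5, 3))
  bt <- attr(ibi, "beat_times_all")
  truth <- sub$truth$beat_times
  expect_equal(length(bt), length(truth))
  # mean absolute interval error against the true IBI series
  expect_lt(mean(abs(ibi$intervals - diff(truth) * 1000)), 15)

  expect_error(reconstruct_bvp_ibi(uniform_series(rep(1, 64 * 30), 64),
                                   filter_spec(0.5, 3)))
  expect_error(filter_spec(0.2, 3))
  expect_error(filter_spec(1.5, 1.0))
})

test_that("distribution-based artifact flagging classifies beats as stated", {
  base <- rep(800, 30)

  one_double <- replace(base, 15, 1600)
  fl <- berntson_detect(ibi_series(cumsum(one_double) / 1000, one_double))
  expect_equal(which(fl != "none"), 15L)
  expect_equal(fl[15], "missing_beat")

  one_half <- replace(base, 15, 400)
  fl2 <- berntson_detect(ibi_series(cumsum(one_half) / 1000, one_half))
  expect_equal(which(fl2 != "none"), 15L)
  expect_equal(fl2[15], "extra_beat")

  fl3 <- berntson_detect(ibi_series(cumsum(base) / 1000, base))
  expect_true(all(fl3 == "none"))

  expect_error(berntson_detect(ibi_from_beats(seq(0, 8, by = 0.8))), "20")
})

test_that("artifact correction interpolates from clean neighbours", {
  base <- rep(800, 30)
  ib <- ibi_series(cumsum(base) / 1000, replace(base, 15, 1600))
  fl <- berntson_detect(ib)
  out <- correct_artifacts(ib, fl)
  expect_gte(out$intervals[15], 790)
  expect_lte(out$intervals[15], 810)
  expect_equal(attr(out, "n_corrected"), sum(fl != "none"))

  clean <- ibi_series(cumsum(base) / 1000, base)
  expect_identical(correct_artifacts(clean, rep("none", 30))$intervals,
                   clean$intervals)
  expect_error(correct_artifacts(clean, rep("artifact", 30)), "50%")
})

test_that("correction restores the mean after injected doublings", {
  set.seed(14)
  n <- 200
  x <- 800 + rnorm(n, sd = 30)
  for (k in c(50, 120, 170)) x[k] <- 2 * x[k]   # missing-beat artifacts
  ib <- ibi_series(cumsum(x) / 1000, x)
  out <- correct_artifacts(ib, berntson_detect(ib))
  clean_mean <- mean(replace(x, c(50, 120, 170), 800))
  expect_lt(abs(mean(out$intervals) - clean_mean), 1)
})

test_that("IBI resampling is pchip on a 4 Hz grid", {
  b <- cumsum(rep(0.8, 20))
  rs <- resample_ibi(ibi_series(b, rep(800, 20)))
  expect_true(all(abs(rs$values - 800) < 1e-9))
  expect_equal(length(rs), floor((b[20] - b[1]) * 4) + 1)
  expect_equal(rs$fs, 4)

  # intervals affine in beat time: pchip reproduces linear data exactly
  b2 <- cumsum(seq(700, 900, length.out = 20)) / 1000
  vals <- 750 + 20 * b2
  rs2 <- resample_ibi(ibi_series(b2, vals))
  expected <- 750 + 20 * (series_time(rs2) + rs2$t0)
  expect_equal(rs2$values, expected, tolerance = 1e-6)
  expect_error(resample_ibi(ibi_series(c(1, 2), c(1000, 1000))), "4 beats")
})

test_that("Lomb-Scargle periodogram matches analytic and classical results", {
  fs <- 4
  t <- (0:(300 * fs - 1)) / fs
  u <- uniform_series(sin(2 * pi * 0.1 * t), fs)
  ls <- lomb_scargle_psd(u)
  expect_equal(ls$freq[which.max(ls$power)], 0.1, tolerance = 0.005)

  const <- lomb_scargle_psd(uniform_series(rep(3, 400), fs))
  expect_lt(max(const$power), 1e-12)

  # classical-periodogram equivalence at Fourier frequencies
  set.seed(8)
  n <- 512
  x <- rnorm(n)
  f1 <- fs / n
  ls2 <- lomb_scargle_psd(uniform_series(x, fs), fmin = f1, fmax = 0.5,
                          df = f1)
  tt <- (0:(n - 1)) / fs
  classical <- vapply(ls2$freq, function(f) {
    Mod(sum((x - mean(x)) * exp(-2i * pi * f * tt)))^2 / n
  }, numeric(1))
  expect_lt(max(abs(ls2$power - classical) / classical), 0.01)
  expect_error(lomb_scargle_psd(uniform_series(rnorm(32), fs)), "64")
})

test_that("HRV metrics match hand arithmetic and band containment", {
  ib <- ibi_series(c(0.8, 1.61, 2.4), c(800, 810, 790))
  m <- hrv_metrics(ib, psd = list(freq = 1, power = 1))
  expect_equal(m$mean_ibi, 800)
  expect_equal(m$sdnn, 10)
  expect_equal(m$rmssd, sqrt((10^2 + (-20)^2) / 2), tolerance = 1e-6)
  expect_equal(m$rmssd, 15.81, tolerance = 1e-3)

  same <- ibi_series(c(0.8, 1.6, 2.4), rep(800, 3))
  m2 <- hrv_metrics(same, psd = list(freq = 1, power = 1))
  expect_equal(m2$sdnn, 0)
  expect_equal(m2$rmssd, 0)

  # interval modulation purely at 0.1 Hz concentrates normalized power in LF
  tk <- 0
  while (tail(tk, 1) < 300) {
    tk <- c(tk, tail(tk, 1) + (800 + 50 * sin(2 * pi * 0.1 * tail(tk, 1))) / 1000)
  }
  m3 <- hrv_metrics(ibi_from_beats(tk))
  expect_gt(m3$lf_nu, 95)
  expect_equal(m3$lf_nu + m3$hf_nu, 100, tolerance = 1e-6)
  expect_error(hrv_metrics(ibi_series(1, 800)), "2 intervals")
})

test_that("ECG and BVP paths agree on motion-free recordings", {
  cfg <- motion_free_config(schedule = short_schedule())
  sub <- simulate_subject(cfg, 55)
  res <- process_subject_hrv(sub$device, sub$gold, sub$schedule)
  g <- res$ibi$gold
  d <- res$ibi$device
  expect_lt(abs(mean(g$intervals) - mean(d$intervals)), 2)
  expect_equal(res$native_capture, 100, tolerance = 1)
})

test_that("artifact rate does not decrease with motion burst rate", {
  rates <- c(0, 3, 6)
  art <- vapply(rates, function(r) {
    ms <- no_motion()
    ms$burst_rate_per_min[] <- r
    total <- 0
    for (s in 1:3) {  # averaged over seeds
      cfg <- synth_config(n_subjects = 1, seed = 3, motion_spec = ms,
                          schedule = short_schedule())
      sub <- simulate_subject(cfg, 100 + s)
      res <- process_subject_hrv(sub$device, sub$gold, sub$schedule)
      q <- res$quality[res$quality$device == "device", ]
      total <- total + 100 * sum(q$n_artifacts) / sum(q$n_beats)
    }
    total / 3
  }, numeric(1))
  expect_true(all(diff(art) >= -1e-9))
})
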