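# Synthetic paired-recording generator. Produces wrist-device streams (BVP
# 64 Hz, EDA 4 Hz, 3-axis accel 32 Hz, gappy native IBI list) and
# gold-standard streams (ECG and EDA at 500 Hz) with full ground truth, so
# every pipeline stage and the validation suite are testable without any
# external recording.

#' Default per-condition specifications for the synthetic cohort
#'
#' `hrv_spec`: integral-pulse-frequency-modulation parameters (population
#' mean IBI and SDNN with between-subject SDs, LF/HF power ratio).
#' `motion_spec`: per-condition accelerometer burst rates (bursts/min),
#' burst amplitude (g), burst duration and carrier frequency range, and the
#' BVP coupling gain. `eda_spec`: per-condition SCR rates, SCR amplitude,
#' tonic level and drift, wrist attenuation, step-artifact counts.
#' `noise_spec`: additive noise SD per channel.
#'
#' @param n_subjects Number of subjects (default 14).
#' @param seed Master seed.
#' @param schedule `condition_schedule` template.
#' @param hrv_spec,motion_spec,eda_spec,noise_spec Named lists overriding
#'   individual defaults.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 14, seed = 1,
                         schedule = default_schedule(),
                         hrv_spec = list(), motion_spec = list(),
                         eda_spec = list(), noise_spec = list()) {
  hrv <- utils::modifyList(list(
    mean_ibi_ms = 800, sdnn_ms = 50, lf_hf_ratio = 2,
    mean_ibi_between_sd_ms = 60, sdnn_between_sd_ms = 10
  ), hrv_spec)
  motion <- utils::modifyList(list(
    burst_rate_per_min = c(Baseline = 0, VideoClip = 0.2, Scream = 1,
                           NRDriving = 2, LRDriving = 3, HRDriving = 4),
    burst_amplitude_g = 0.4, burst_duration_s = 3,
    burst_freq_hz = c(2, 4), coupling_gain = 3
  ), motion_spec)
  eda <- utils::modifyList(list(
    scr_rate_per_min = c(Baseline = 2, VideoClip = 4, Scream = 6,
                         NRDriving = 3, LRDriving = 4, HRDriving = 5),
    scr_amp_uS = 0.5, scr_amp_sd_uS = 0.15,
    tonic_base_uS = 6, drift_uS_per_min = 0.1,
    wrist_attenuation = 0.5,
    artifact_steps_wrist = 3, artifact_steps_gold = 1,
    step_amp_uS = 2, nonresponsive_prob = 0.2
  ), eda_spec)
  noise <- utils::modifyList(list(
    ecg_sd = 0.02, bvp_sd = 0.05, eda_sd_uS = 0.02, accel_sd_g = 0.02
  ), noise_spec)
  stopifnot(all(schedule$entries$stop_s > schedule$entries$start_s),
            eda$wrist_attenuation > 0, eda$wrist_attenuation <= 1,
            n_subjects >= 1)
  structure(
    list(n_subjects = n_subjects, seed = as.integer(seed),
         schedule = schedule, hrv_spec = hrv, motion_spec = motion,
         eda_spec = eda, noise_spec = noise),
    class = "synth_config"
  )
}

#' Generate ground-truth beat times by integral pulse frequency modulation
#'
#' A modulating signal — the sum of two band-limited Gaussian components
#' centered in the 0.04-0.15 Hz and 0.15-0.4 Hz bands with the configured
#' power ratio and a total coefficient of variation of `sdnn_ms /
#' mean_ibi_ms` — drives an integrate-and-fire scheme: a beat is emitted at
#' each integer crossing of the integrated instantaneous rate. With zero
#' modulation the beats are perfectly periodic.
#'
#' @param hrv_spec List with `mean_ibi_ms`, `sdnn_ms`, `lf_hf_ratio`.
#' @param duration_s Recording duration (>= 60 s).
#' @param seed RNG seed.
#' @return Numeric vector of beat times in seconds; attribute `modulation`
#'   holds the modulating signal (`t`, `m`).
#' @export
generate_beat_times <- function(hrv_spec, duration_s, seed) {
  stopifnot(duration_s >= 60)
  T0 <- hrv_spec$mean_ibi_ms / 1000
  cv <- hrv_spec$sdnn_ms / hrv_spec$mean_ibi_ms
  if (cv > 0.3) {
    stop("infeasible configuration: SDNN target ", hrv_spec$sdnn_ms,
         " ms unreachable for mean IBI ", hrv_spec$mean_ibi_ms, " ms")
  }
  set.seed(seed)
  fs <- 8
  n <- ceiling(duration_s * fs) + 1L
  tg <- (seq_len(n) - 1L) / fs
  if (cv > 0) {
    ratio <- hrv_spec$lf_hf_ratio
    lf <- band_limited_noise(n, fs, 0.04, 0.15)
    hf <- band_limited_noise(n, fs, 0.15, 0.4)
    m <- lf * sqrt(cv^2 * ratio / (1 + ratio)) + hf * sqrt(cv^2 / (1 + ratio))
    m <- pmax(pmin(m, 0.9), -0.9)
  } else {
    m <- rep(0, n)
  }
  rate <- (1 + m) / T0
  y <- pracma::cumtrapz(tg, rate)[, 1L]
  nb <- floor(max(y))
  if (nb < 1L) return(structure(numeric(0), modulation = list(t = tg, m = m)))
  beats <- stats::approx(y, tg, xout = seq_len(nb), ties = "ordered")$y
  structure(beats, modulation = list(t = tg, m = m))
}

# unit-variance Gaussian noise restricted to [f_lo, f_hi] by FFT masking
band_limited_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)  # two-sided
  W[f < f_lo | f > f_hi] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) rep(0, n) else x / s
}

#' Synthesize a gold-standard ECG from beat times
#'
#' One sharp template deflection (Gaussian R wave, 10 ms SD, unit
#' amplitude) per beat plus white noise. With an empty beat list the output
#' is flat noise.
#'
#' @param beat_times Beat times in seconds.
#' @param fs Sampling rate (default 500 Hz).
#' @param noise_sd Additive noise SD (must be <= 0.2 so the deflection
#'   stays at least five times the noise floor).
#' @param duration_s Recording length; defaults to the last beat + 1 s.
#' @param seed RNG seed for the noise.
#' @return A `uniform_series`.
#' @export
synth_ecg <- function(beat_times, fs = 500, noise_sd = 0.02,
                      duration_s = NULL, seed = 1) {
  if (noise_sd > 0.2) stop("noise_sd too large: QRS must be >= 5x noise SD")
  if (is.null(duration_s)) {
    duration_s <- if (length(beat_times)) max(beat_times) + 1 else 10
  }
  set.seed(seed)
  n <- ceiling(duration_s * fs)
  x <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else rep(0, n)
  if (length(beat_times)) {
    sigma <- 0.010
    tk <- seq(-4 * sigma, 4 * sigma, by = 1 / fs)
    template <- exp(-tk^2 / (2 * sigma^2))
    for (bt in beat_times) {
      i0 <- round(bt * fs) + 1L
      idx <- i0 + seq_along(template) - 1L - (length(template) %/% 2L)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + template[ok]
    }
  }
  uniform_series(x, fs = fs)
}

#' Synthesize paired BVP and accelerometer streams with motion bursts
#'
#' The BVP is a per-beat pulse template (fast systolic rise, slow diastolic
#' decay) plus a corruption term proportional to the high-pass-filtered
#' acceleration magnitude inside motion bursts, plus noise. The
#' accelerometer carries gravity on one axis; bursts are Hann-tapered
#' sinusoids on the gravity axis whose per-condition rate follows
#' `motion_spec`, so the magnitude deflection is linear in the burst
#' amplitude. The burst windows are the injected BVP artifact intervals.
#'
#' @param beat_times Ground-truth beat times (s).
#' @param motion_spec Motion specification (see [synth_config()]).
#' @param schedule `condition_schedule` covering the beat-time span.
#' @param seed RNG seed.
#' @param noise_spec Channel noise SDs (see [synth_config()]).
#' @return List with `bvp` (64 Hz `uniform_series`), `accel` (32 Hz 3-axis
#'   `uniform_series`, g), and `artifact_intervals` (data frame
#'   `start_s`/`stop_s`).
#' @export
synth_bvp_accel <- function(beat_times, motion_spec, schedule, seed,
                            noise_spec = list(bvp_sd = 0.05,
                                              accel_sd_g = 0.02)) {
  set.seed(seed)
  span <- schedule_span(schedule)
  if (length(beat_times) && max(beat_times) > span[2L] + 1e-9) {
    stop("schedule does not cover the beat-time span")
  }
  duration <- span[2L]
  fs_b <- 64
  fs_a <- 32
  nb <- ceiling(duration * fs_b)
  na <- ceiling(duration * fs_a)
  tb <- (seq_len(nb) - 1L) / fs_b
  ta <- (seq_len(na) - 1L) / fs_a

  # motion bursts per condition
  bursts <- list()
  rate <- motion_spec$burst_rate_per_min
  for (i in seq_len(nrow(schedule$entries))) {
    e <- schedule$entries[i, ]
    r <- rate[[e$label]]
    if (is.null(r) || r <= 0) next
    k <- stats::rpois(1, r * (e$stop_s - e$start_s) / 60)
    if (k < 1) next
    starts <- sort(stats::runif(k, e$start_s,
                                max(e$start_s, e$stop_s - motion_spec$burst_duration_s)))
    for (s in starts) {
      bursts[[length(bursts) + 1L]] <- c(s, min(s + motion_spec$burst_duration_s,
                                                e$stop_s))
    }
  }
  bursts <- merge_intervals(bursts)

  # accel: gravity on z, bursts as tapered sinusoids on z
  az <- rep(1, na)
  for (j in seq_len(nrow(bursts))) {
    idx <- which(ta >= bursts$start_s[j] & ta < bursts$stop_s[j])
    if (length(idx) < 2L) next
    f <- stats::runif(1, motion_spec$burst_freq_hz[1], motion_spec$burst_freq_hz[2])
    ph <- stats::runif(1, 0, 2 * pi)
    taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(idx)))
    az[idx] <- az[idx] +
      motion_spec$burst_amplitude_g * taper * sin(2 * pi * f * ta[idx] + ph)
  }
  sd_a <- noise_spec$accel_sd_g
  acc <- cbind(
    x = if (sd_a > 0) stats::rnorm(na, sd = sd_a) else rep(0, na),
    y = if (sd_a > 0) stats::rnorm(na, sd = sd_a) else rep(0, na),
    z = az + (if (sd_a > 0) stats::rnorm(na, sd = sd_a) else 0)
  )
  accel <- uniform_series(acc, fs = fs_a, units = "g")

  # BVP: pulse template per beat
  bvp <- rep(0, nb)
  tk <- seq(0, 0.9, by = 1 / fs_b)
  template <- (tk / 0.12)^2 * exp(-tk / 0.12)
  template <- template / max(template)
  for (bt in beat_times) {
    i0 <- floor(bt * fs_b) + 1L
    idx <- i0 + seq_along(template) - 1L
    ok <- idx >= 1L & idx <= nb
    bvp[idx[ok]] <- bvp[idx[ok]] + template[ok]
  }

  # corruption: coupling_gain x high-passed accel magnitude, inside bursts
  if (nrow(bursts)) {
    mag <- sqrt(rowSums(acc^2))
    bf <- signal::butter(3, 0.1 / (fs_a / 2), type = "high")
    mag_hp <- signal::filtfilt(bf, mag)
    gate <- rep(0, na)
    for (j in seq_len(nrow(bursts))) {
      gate[ta >= bursts$start_s[j] & ta < bursts$stop_s[j]] <- 1
    }
    corr64 <- stats::approx(ta, mag_hp * gate, xout = tb, rule = 2)$y
    bvp <- bvp + motion_spec$coupling_gain * corr64
  }
  if (noise_spec$bvp_sd > 0) bvp <- bvp + stats::rnorm(nb, sd = noise_spec$bvp_sd)

  list(
    bvp = uniform_series(bvp, fs = fs_b),
    accel = accel,
    artifact_intervals = bursts
  )
}

merge_intervals <- function(lst) {
  if (!length(lst)) return(data.frame(start_s = numeric(0), stop_s = numeric(0)))
  iv <- do.call(rbind, lst)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  merged <- iv[1L, , drop = FALSE]
  for (j in seq_len(nrow(iv))[-1L]) {
    last <- nrow(merged)
    if (iv[j, 1L] <= merged[last, 2L]) {
      merged[last, 2L] <- max(merged[last, 2L], iv[j, 2L])
    } else {
      merged <- rbind(merged, iv[j, , drop = FALSE])
    }
  }
  data.frame(start_s = merged[, 1L], stop_s = merged[, 2L])
}

#' Emulate the device's partial native IBI output
#'
#' The wrist device emits an IBI entry only for beats it trusts; beats
#' falling inside motion-burst intervals are dropped, producing the gappy
#' native stream the reconstruction algorithm mines for artifact-free
#' segments.
#'
#' @param beat_times Ground-truth beat times (s).
#' @param artifact_intervals Data frame `start_s`/`stop_s` of corrupted
#'   windows.
#' @return An `ibi_series`; attribute `fraction_retained` reports the kept
#'   fraction of true intervals.
#' @export
synth_native_ibi <- function(beat_times, artifact_intervals) {
  full <- ibi_from_beats(beat_times)
  if (!length(full$beat_times)) {
    out <- full
    attr(out, "fraction_retained") <- NA_real_
    return(out)
  }
  drop <- rep(FALSE, length(full$beat_times))
  if (!is.null(artifact_intervals) && nrow(artifact_intervals)) {
    for (j in seq_len(nrow(artifact_intervals))) {
      drop <- drop | (full$beat_times >= artifact_intervals$start_s[j] &
                        full$beat_times <= artifact_intervals$stop_s[j])
    }
  }
  out <- ibi_series(full$beat_times[!drop], full$intervals[!drop],
                    full$flags[!drop])
  attr(out, "fraction_retained") <- mean(!drop)
  out
}

#' Synthesize an EDA recording with known SCR events and step artifacts
#'
#' Tonic (baseline plus drift) + sum of bi-exponential skin conductance
#' responses (rise about 1 s, decay about 4 s; wrist amplitudes scaled by
#' the attenuation factor) + white noise + boxcar step artifacts emulating
#' electrode contact losses. With the same seed the finger and wrist
#' recordings share the same underlying SCR events.
#'
#' @param eda_spec EDA specification (see [synth_config()]).
#' @param schedule `condition_schedule`.
#' @param site `"finger"` (500 Hz) or `"wrist"` (4 Hz).
#' @param seed RNG seed.
#' @param noise_sd Additive noise SD in microsiemens.
#' @param responsive When `FALSE` no SCRs are generated (a non-responsive
#'   subject).
#' @return List with `eda` (`uniform_series`, microsiemens) and `truth`
#'   (SCR times/amplitudes, artifact intervals, tonic component).
#' @export
synth_eda <- function(eda_spec, schedule, site = c("finger", "wrist"),
                      seed = 1, noise_sd = 0.02, responsive = TRUE) {
  site <- match.arg(site)
  set.seed(seed)
  fs <- if (site == "wrist") 4 else 500
  duration <- schedule_span(schedule)[2L]
  n <- ceiling(duration * fs)
  t <- (seq_len(n) - 1L) / fs

  tonic <- eda_spec$tonic_base_uS + (eda_spec$drift_uS_per_min / 60) * t

  # SCR events (site-independent draws; wrist attenuates amplitudes)
  scr_times <- numeric(0)
  scr_amps <- numeric(0)
  if (responsive) {
    for (i in seq_len(nrow(schedule$entries))) {
      e <- schedule$entries[i, ]
      r <- eda_spec$scr_rate_per_min[[e$label]]
      if (is.null(r) || r <= 0) next
      k <- stats::rpois(1, r * (e$stop_s - e$start_s) / 60)
      if (k < 1) next
      scr_times <- c(scr_times, sort(stats::runif(k, e$start_s, e$stop_s - 10)))
      scr_amps <- c(scr_amps,
                    pmax(0.1, stats::rnorm(k, eda_spec$scr_amp_uS,
                                           eda_spec$scr_amp_sd_uS)))
    }
  }
  gain <- if (site == "wrist") eda_spec$wrist_attenuation else 1
  x <- tonic
  if (length(scr_times)) {
    tk <- seq(0, 30, by = 1 / fs)
    kern <- exp(-tk / 4) - exp(-tk / 1)
    kern <- kern / max(kern)
    for (j in seq_along(scr_times)) {
      i0 <- floor(scr_times[j] * fs) + 1L
      idx <- i0 + seq_along(kern) - 1L
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + gain * scr_amps[j] * kern[ok]
    }
  }

  # boxcar step artifacts (contact losses)
  n_steps <- if (site == "wrist") eda_spec$artifact_steps_wrist else
    eda_spec$artifact_steps_gold
  artifacts <- data.frame(start_s = numeric(0), stop_s = numeric(0))
  if (n_steps > 0) {
    starts <- sort(stats::runif(n_steps, 10, duration - 30))
    durs <- stats::runif(n_steps, 5, 15)
    signs <- sample(c(-1, 1), n_steps, replace = TRUE)
    keep <- c(TRUE, diff(starts) > 30)  # keep artifacts well separated
    starts <- starts[keep]; durs <- durs[keep]; signs <- signs[keep]
    for (j in seq_along(starts)) {
      x[t >= starts[j] & t < starts[j] + durs[j]] <-
        x[t >= starts[j] & t < starts[j] + durs[j]] +
        signs[j] * eda_spec$step_amp_uS
    }
    artifacts <- data.frame(start_s = starts, stop_s = starts + durs)
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)

  list(
    eda = uniform_series(x, fs = fs, units = "uS"),
    truth = list(
      scr_times = scr_times,
      scr_amplitudes = gain * scr_amps,
      artifact_intervals = artifacts,
      tonic = uniform_series(tonic, fs = fs, units = "uS"),
      responsive = responsive && length(scr_times) > 0
    )
  )
}

#' Simulate one subject's paired recording
#'
#' Draws subject-level HRV/EDA characteristics from the population
#' specification, then generates all device and gold-standard channels plus
#' the ground truth.
#'
#' @param config A `synth_config`.
#' @param subject_seed Integer seed for this subject.
#' @return List with `device` (bvp, eda, accel, native_ibi), `gold`
#'   (ecg, eda), `schedule`, and `truth`.
#' @export
simulate_subject <- function(config, subject_seed) {
  set.seed(subject_seed)
  hs <- config$hrv_spec
  hs$mean_ibi_ms <- stats::rnorm(1, hs$mean_ibi_ms, hs$mean_ibi_between_sd_ms)
  hs$mean_ibi_ms <- min(max(hs$mean_ibi_ms, 550), 1200)
  hs$sdnn_ms <- max(10, stats::rnorm(1, hs$sdnn_ms, hs$sdnn_between_sd_ms))
  responsive <- stats::runif(1) >= config$eda_spec$nonresponsive_prob
  seeds <- sample.int(.Machine$integer.max - 1L, 5L)

  duration <- schedule_span(config$schedule)[2L]
  beats <- generate_beat_times(hs, duration, seed = seeds[1L])
  beats <- beats[beats < duration - 0.5]
  ecg <- synth_ecg(beats, fs = 500, noise_sd = config$noise_spec$ecg_sd,
                   duration_s = duration, seed = seeds[2L])
  ba <- synth_bvp_accel(beats, config$motion_spec, config$schedule,
                        seed = seeds[3L], noise_spec = config$noise_spec)
  native <- synth_native_ibi(beats, ba$artifact_intervals)
  eda_g <- synth_eda(config$eda_spec, config$schedule, site = "finger",
                     seed = seeds[4L], noise_sd = config$noise_spec$eda_sd_uS,
                     responsive = responsive)
  eda_w <- synth_eda(config$eda_spec, config$schedule, site = "wrist",
                     seed = seeds[4L], noise_sd = config$noise_spec$eda_sd_uS,
                     responsive = responsive)

  list(
    device = list(bvp = ba$bvp, eda = eda_w$eda, accel = ba$accel,
                  native_ibi = native),
    gold = list(ecg = ecg, eda = eda_g$eda),
    schedule = config$schedule,
    truth = list(
      beat_times = as.numeric(beats),
      subject_hrv = hs,
      bvp_artifact_intervals = ba$artifact_intervals,
      native_fraction_retained = attr(native, "fraction_retained"),
      eda_gold = eda_g$truth,
      eda_wrist = eda_w$truth,
      responsive = responsive
    )
  )
}

#' Simulate a cohort of paired recordings
#'
#' @param config A `synth_config`. The master seed determines every
#'   subject; identical configs yield identical cohorts.
#' @return List of subject recordings (see [simulate_subject()]), with the
#'   per-subject seeds as attribute `subject_seeds`.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  out <- lapply(seeds, function(s) simulate_subject(config, s))
  names(out) <- sprintf("S%02d", seq_along(out))
  attr(out, "subject_seeds") <- seeds
  out
}
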