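# HRV pipeline: ECG R-peak detection (Pan-Tompkins), mining of
# artifact-free segments from the device-native IBI stream, selection of a
# subject-specific band-pass by PSD subtraction of the acceleration
# magnitude from the BVP, diastolic foot-point beat detection,
# distribution-based (Berntson) artifact flagging and interpolation, 4 Hz
# resampling, Lomb-Scargle spectra, and the five HRV parameters.

#' Subject-specific band-pass filter specification
#'
#' @param low_cut,high_cut Cut-off frequencies in Hz. Must satisfy
#'   `0.4 <= low_cut < high_cut <= 3.1` (the 0.5-3 Hz physiological band
#'   widened by the 0.1 Hz safety margin).
#' @param order Butterworth order (default 3).
#' @param margin Safety margin in Hz already applied to the cut-offs.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut, high_cut, order = 3, margin = 0.1) {
  if (!(low_cut >= 0.4 - 1e-9 && low_cut < high_cut && high_cut <= 3.1 + 1e-9)) {
    stop("filter_spec cut-offs must satisfy 0.4 <= low < high <= 3.1 Hz")
  }
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = order, margin = margin),
            class = "filter_spec")
}

#' Detect ECG R peaks (Pan-Tompkins)
#'
#' Band-pass (5-15 Hz), derivative, squaring, moving-window integration
#' (150 ms) and adaptive signal/noise thresholding with search-back, with
#' R-peak times refined on the raw ECG. Returns the inter-beat intervals of
#' successive peaks.
#'
#' @param ecg `uniform_series` sampled at >= 200 Hz.
#' @param refractory_s Minimum separation between detected beats (s).
#' @return An `ibi_series`. Attribute `beat_times_all` holds all detected
#'   R-peak times (including the first beat, which carries no interval).
#' @export
detect_r_peaks <- function(ecg, refractory_s = 0.2) {
  stopifnot(inherits(ecg, "uniform_series"))
  fs <- ecg$fs
  if (fs < 200) stop("Pan-Tompkins requires fs >= 200 Hz")
  x <- ecg$values
  if (length(x) < 2 * fs) stop("segment shorter than filter warm-up (2 s)")

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  der <- c(0, diff(bp)) * fs
  sq <- der^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  mwi[is.na(mwi)] <- 0

  # suppress sub-threshold ripple before candidate search (the adaptive
  # threshold below does the real signal/noise discrimination)
  mwi[mwi < 0.01 * max(mwi)] <- 0
  cand <- find_peaks(mwi, min_dist = max(1L, round(refractory_s * fs)))
  if (!length(cand)) return(empty_ibi())

  init <- mwi[seq_len(min(length(mwi), 2L * round(fs)))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  thr <- npki + 0.25 * (spki - npki)

  accepted <- integer(0)
  rr_recent <- numeric(0)
  for (p in cand) {
    if (mwi[p] > thr) {
      accepted <- c(accepted, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(accepted) > 1L) {
        rr_recent <- c(rr_recent, p - accepted[length(accepted) - 1L])
        if (length(rr_recent) > 8L) rr_recent <- utils::tail(rr_recent, 8L)
      }
    } else {
      # search-back: if the expected beat is overdue, accept on half threshold
      overdue <- length(accepted) && length(rr_recent) &&
        (p - accepted[length(accepted)]) > 1.66 * mean(rr_recent)
      if (overdue && mwi[p] > thr / 2) {
        accepted <- c(accepted, p)
        spki <- 0.25 * mwi[p] + 0.75 * spki
        rr_recent <- c(rr_recent, p - accepted[length(accepted) - 1L])
        if (length(rr_recent) > 8L) rr_recent <- utils::tail(rr_recent, 8L)
      } else {
        npki <- 0.125 * mwi[p] + 0.875 * npki
      }
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (!length(accepted)) return(empty_ibi())

  # refine each fiducial on the raw ECG (MWI lags by roughly w/2 + deriv lag)
  half <- round(0.150 * fs)
  peaks <- vapply(accepted, function(p) {
    lo <- max(1L, p - half)
    hi <- min(length(x), p + round(0.05 * fs))
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) > 1L) {
    peaks <- peaks[c(TRUE, diff(peaks) > refractory_s * fs / 2)]
  }
  beat_times <- (peaks - 1L) / fs
  out <- ibi_from_beats(beat_times)
  attr(out, "beat_times_all") <- beat_times
  out
}

empty_ibi <- function() {
  out <- ibi_series(numeric(0), numeric(0), character(0))
  attr(out, "beat_times_all") <- numeric(0)
  out
}

#' Mine artifact-free segments from the device-native IBI stream
#'
#' The device emits an IBI entry only when it trusts the underlying pulse
#' wave, so runs where every interval exactly bridges the gap to the
#' previous beat mark stretches free of motion corruption. Runs of at least
#' `min_run` consecutive intervals are returned.
#'
#' @param native_ibi `ibi_series` as recorded by the device.
#' @param min_run Minimum run length in intervals (default 10).
#' @param tol_ms Contiguity tolerance in ms (default 1).
#' @return Data frame with columns `start_s`, `stop_s`, `n_intervals`
#'   (possibly zero rows).
#' @export
find_artifact_free_segments <- function(native_ibi, min_run = 10, tol_ms = 1) {
  t <- native_ibi$beat_times
  v <- native_ibi$intervals
  n <- length(t)
  empty <- data.frame(start_s = numeric(0), stop_s = numeric(0),
                      n_intervals = integer(0))
  if (n == 0L) return(empty)
  contig <- c(FALSE, abs((t[-1L] - t[-n]) * 1000 - v[-1L]) <= tol_ms)
  runs <- list()
  k0 <- 1L
  for (k in seq_len(n)) {
    if (!contig[k]) k0 <- k
    last <- k == n || !contig[k + 1L]
    if (last) {
      len <- k - k0 + 1L
      if (len >= min_run) {
        runs[[length(runs) + 1L]] <-
          data.frame(start_s = t[k0] - v[k0] / 1000, stop_s = t[k],
                     n_intervals = len)
      }
    }
  }
  if (!length(runs)) return(empty)
  do.call(rbind, runs)
}

simple_periodogram <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  half <- floor(n / 2)
  list(freq = (0:half) * fs / n, power = P[1:(half + 1L)])
}

#' Select the subject-specific cardiac band by PSD subtraction
#'
#' For each artifact-free segment, the rectangular-window periodogram of the
#' BVP and of the conditioned acceleration magnitude are each scaled by
#' their own maximum; the acceleration PSD (interpolated onto the BVP
#' frequency grid) is subtracted and the argmax of the difference is taken
#' as the segment's fundamental frequency. Fundamentals are retained only
#' inside the physiological 0.5-3 Hz range; the subject band is their
#' min/max widened by the safety margin. With no retained fundamental, the
#' default physiological band is used with a warning.
#'
#' @param bvp BVP `uniform_series` (full recording).
#' @param accel_mag Conditioned acceleration magnitude `uniform_series`
#'   (see [accel_magnitude()]).
#' @param segments Data frame from [find_artifact_free_segments()].
#' @param phys_band Physiological range in Hz, default `c(0.5, 3)`.
#' @param margin Safety margin in Hz, default 0.1.
#' @param order Filter order carried into the returned spec.
#' @param window_s Long artifact-free segments are chopped into windows of
#'   this length (s) before fundamental extraction, so that the collected
#'   fundamentals track the heart-rate range rather than its long-run
#'   average; windows shorter than 8 s are dropped.
#' @return A `filter_spec`; attribute `fundamentals` holds the per-segment
#'   retained fundamentals, attribute `fallback` records whether the
#'   default band was used.
#' @export
subject_band_from_psd_subtraction <- function(bvp, accel_mag, segments,
                                              phys_band = c(0.5, 3),
                                              margin = 0.1, order = 3,
                                              window_s = 30) {
  if (nrow(segments) < 1L) stop("at least one artifact-free segment required")
  segments <- chop_segments(segments, window_s)
  fund <- numeric(0)
  for (i in seq_len(nrow(segments))) {
    sb <- slice_span(bvp, segments$start_s[i], segments$stop_s[i])
    sa <- slice_span(accel_mag, segments$start_s[i], segments$stop_s[i])
    if (length(sb) < 8L || length(sa) < 8L) next
    pb <- simple_periodogram(sb, bvp$fs)
    pa <- simple_periodogram(sa, accel_mag$fs)
    pbn <- pb$power / max(pb$power)
    pan <- stats::approx(pa$freq, pa$power / max(pa$power), xout = pb$freq,
                         rule = 2)$y
    diffp <- pbn - pan
    keep <- pb$freq > 0
    f0 <- pb$freq[keep][which.max(diffp[keep])]
    if (f0 >= phys_band[1] && f0 <= phys_band[2]) fund <- c(fund, f0)
  }
  if (!length(fund)) {
    warning("no in-range fundamental frequency; falling back to the ",
            "default physiological band")
    out <- filter_spec(phys_band[1], phys_band[2], order = order,
                       margin = margin)
    attr(out, "fundamentals") <- numeric(0)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  low <- max(min(fund) - margin, phys_band[1] - margin)
  high <- min(max(fund) + margin, phys_band[2] + margin)
  out <- filter_spec(low, high, order = order, margin = margin)
  attr(out, "fundamentals") <- fund
  attr(out, "fallback") <- FALSE
  out
}

slice_span <- function(x, start_s, stop_s) {
  t <- series_time(x)
  x$values[t >= start_s & t < stop_s]
}

chop_segments <- function(segments, window_s, min_s = 8) {
  out <- list()
  for (i in seq_len(nrow(segments))) {
    cuts <- seq(segments$start_s[i], segments$stop_s[i], by = window_s)
    if (cuts[length(cuts)] < segments$stop_s[i]) {
      cuts <- c(cuts, segments$stop_s[i])
    }
    for (j in seq_len(length(cuts) - 1L)) {
      if (cuts[j + 1L] - cuts[j] >= min_s) {
        out[[length(out) + 1L]] <- data.frame(start_s = cuts[j],
                                              stop_s = cuts[j + 1L])
      }
    }
  }
  if (!length(out)) return(segments)
  do.call(rbind, out)
}

#' Reconstruct inter-beat intervals from the BVP foot points
#'
#' Applies the zero-phase subject-specific Butterworth band-pass, then takes
#' the diastolic foot points (local minima preceding each systolic upstroke)
#' as beat fiducials, with a minimum separation of `1 / high_cut` seconds
#' and a prominence floor expressed as a fraction of the filtered signal's
#' inter-quartile range.
#'
#' @param bvp BVP `uniform_series`.
#' @param spec `filter_spec` from [subject_band_from_psd_subtraction()].
#' @param min_prominence_frac Prominence threshold as a fraction of the IQR,
#'   default 0.3.
#' @param refine Refine each foot point on a lightly low-passed version of
#'   the raw waveform with parabolic sub-sample interpolation (default
#'   `TRUE`). The narrow subject band is excellent at locating beats but
#'   distorts their fine timing; the refinement restores it.
#' @return An `ibi_series` with attribute `beat_times_all`.
#' @export
reconstruct_bvp_ibi <- function(bvp, spec, min_prominence_frac = 0.3,
                                refine = TRUE) {
  stopifnot(inherits(spec, "filter_spec"))
  fs <- bvp$fs
  bf <- signal::butter(spec$order,
                       c(spec$low_cut, spec$high_cut) / (fs / 2),
                       type = "pass")
  filt <- signal::filtfilt(bf, bvp$values - mean(bvp$values))
  prom <- min_prominence_frac * stats::IQR(filt)
  if (prom <= 0) stop("fewer than 3 beats detected in BVP (flat signal)")
  # one minimum per cardiac cycle survives the narrow band; the separation
  # floor is set below 1/high_cut because the per-window fundamentals track
  # average rate, so the fastest individual beats run above high_cut
  feet <- find_peaks(-filt,
                     min_dist = max(1L, round(0.7 * fs / spec$high_cut)),
                     min_prominence = prom)
  if (length(feet) < 3L) stop("fewer than 3 beats detected in BVP")

  beat_times <- if (refine) {
    refine_feet(bvp$values, fs, feet, spec)
  } else {
    (feet - 1L) / fs
  }
  # filter edge transients can fake a foot right at the signal borders
  dur <- n_samples(bvp) / fs
  beat_times <- beat_times[beat_times > 0.5 & beat_times < dur - 0.5]
  out <- ibi_from_beats(beat_times)
  attr(out, "beat_times_all") <- beat_times
  out
}

# Sub-sample beat refinement by cross-correlating the drift-removed raw
# waveform with the subject's ensemble-average pulse around each candidate
# foot. The narrow-band candidate grid locates beats; the template match
# restores their fine timing, which the narrow filter distorts.
refine_feet <- function(raw, fs, feet, spec,
                        pre_s = 0.10, post_s = 0.40, lag_s = 0.20) {
  hf <- signal::butter(2, 0.3 / (fs / 2), type = "high")
  sm <- signal::filtfilt(hf, raw)
  if (fs / 2 > 8) {  # the pulse template carries little energy above ~5 Hz
    lf <- signal::butter(3, 6 / (fs / 2), type = "low")
    sm <- signal::filtfilt(lf, sm)
  }
  n <- length(sm)
  w_pre <- round(pre_s * fs)
  w_post <- round(post_s * fs)
  K <- w_pre + w_post + 1L
  full <- feet > w_pre & feet + w_post <= n
  if (sum(full) < 5L || K >= n) return((feet - 1L) / fs)
  idx <- vapply(feet[full], function(i) (i - w_pre):(i + w_post),
                integer(K))
  templ <- rowMeans(matrix(sm[idx], nrow = K))
  templ <- templ - mean(templ)
  # running dot products of the signal with the template, all window starts
  cc <- stats::convolve(sm, templ, conj = TRUE, type = "filter")
  # cc[t] corresponds to the window starting at sample t
  lagmax <- round(lag_s * fs)
  beat_times <- vapply(feet, function(i) {
    c0 <- i - w_pre  # window start aligned with the candidate foot
    lo <- max(1L, c0 - lagmax)
    hi <- min(length(cc), c0 + lagmax)
    if (lo >= hi) return((i - 1L) / fs)
    j <- lo + which.max(cc[lo:hi]) - 1L
    delta <- 0
    if (j > 1L && j < length(cc)) {
      den <- cc[j - 1L] - 2 * cc[j] + cc[j + 1L]
      if (den < 0) delta <- max(min(0.5 * (cc[j - 1L] - cc[j + 1L]) / den,
                                    0.5), -0.5)
    }
    (j + w_pre - 1L + delta) / fs
  }, numeric(1))
  beat_times <- sort(beat_times)
  beat_times[c(TRUE, diff(beat_times) > 0.5 / spec$high_cut)]
}

#' Flag IBI artifacts from the distribution of successive differences
#'
#' Beat-to-beat differences caused by detection artifacts are large relative
#' to normal heart-period variability. The robust spread of successive
#' interval differences (MAD scaled to the normal SD) times a multiplier
#' sets the criterion; an interval whose differences to both neighbours
#' exceed it is flagged, and classified as a missing beat when it is about
#' twice the local median, an extra beat when about half, otherwise as a
#' generic artifact.
#'
#' @param ibi `ibi_series` with at least 20 intervals.
#' @param multiplier Criterion multiplier on the robust SD (default 4).
#' @param window Local-median window in beats (odd, default 9).
#' @param floor_ms Lower bound on the criterion so that near-constant
#'   series are not flagged wholesale (default 50 ms).
#' @return Character vector of flags, one per interval.
#' @export
berntson_detect <- function(ibi, multiplier = 4, window = 9, floor_ms = 50) {
  x <- ibi$intervals
  n <- length(x)
  if (n < 20L) stop("berntson_detect requires >= 20 intervals")
  d <- diff(x)
  crit <- max(stats::mad(d) * multiplier, floor_ms)  # mad() is MAD/0.6745
  left <- c(Inf, abs(d))    # |x_i - x_{i-1}|
  right <- c(abs(d), Inf)   # |x_{i+1} - x_i|
  dev <- pmin(left, right)  # both neighbours must disagree
  dev[1L] <- right[1L]
  dev[n] <- left[n]
  flagged <- dev > crit
  flags <- rep("none", n)
  if (any(flagged)) {
    med <- stats::runmed(x, k = min(window, n - (1 - n %% 2)))
    ratio <- x / med
    flags[flagged & abs(ratio - 2) <= 0.5] <- "missing_beat"
    flags[flagged & abs(ratio - 0.5) <= 0.2] <- "extra_beat"
    flags[flagged & flags == "none"] <- "artifact"
  }
  flags
}

#' Replace flagged intervals by interpolation from clean neighbours
#'
#' Flagged intervals are removed and re-estimated by a natural cubic spline
#' over beat index fitted to the unflagged intervals. The number of
#' corrected intervals is recorded for the artifact-rate statistics.
#'
#' @param ibi `ibi_series`.
#' @param flags Flags from [berntson_detect()] (plus any manual overrides).
#' @return An `ibi_series` with corrected interval values, original flags
#'   retained, and attribute `n_corrected`.
#' @export
correct_artifacts <- function(ibi, flags = ibi$flags) {
  n <- length(ibi$intervals)
  stopifnot(length(flags) == n)
  bad <- flags != "none"
  if (sum(bad) > n / 2) stop("more than 50% of intervals flagged; series unusable")
  vals <- ibi$intervals
  if (any(bad)) {
    idx <- seq_len(n)
    vals[bad] <- stats::spline(idx[!bad], vals[!bad], xout = idx[bad],
                               method = "natural")$y
  }
  out <- ibi_series(ibi$beat_times, vals, flags)
  attr(out, "n_corrected") <- sum(bad)
  out
}

#' Resample an IBI series onto a uniform grid
#'
#' Shape-preserving piecewise-cubic (monotone Hermite, pchip) interpolation
#' of interval value against beat time, evaluated on a uniform grid from the
#' first to the last beat.
#'
#' @param ibi `ibi_series` with >= 4 entries.
#' @param fs Target rate in Hz (default 4).
#' @return A `uniform_series` of interval values in ms.
#' @export
resample_ibi <- function(ibi, fs = 4) {
  t <- ibi$beat_times
  if (length(t) < 4L) stop("resample_ibi requires >= 4 beats")
  grid <- t[1L] + (0:floor((t[length(t)] - t[1L]) * fs)) / fs
  y <- pracma::pchip(t, ibi$intervals, grid)
  uniform_series(y, fs = fs, t0 = t[1L], units = "ms")
}

#' Lomb-Scargle power spectral density
#'
#' Classical Lomb-Scargle periodogram of the mean-subtracted series on a
#' fixed frequency grid (default 0.005-0.5 Hz in 0.005 Hz steps). On a
#' uniform grid it coincides with the classical periodogram.
#'
#' @param x A `uniform_series`, or a list with elements `t` (s) and `y`.
#' @param fmin,fmax,df Frequency grid in Hz.
#' @return List with `freq` and `power`.
#' @export
lomb_scargle_psd <- function(x, fmin = 0.005, fmax = 0.5, df = 0.005) {
  if (inherits(x, "uniform_series")) {
    t <- series_time(x)
    y <- x$values
  } else {
    t <- x$t
    y <- x$y
  }
  if (length(y) < 64L) stop("lomb_scargle_psd requires >= 64 samples")
  y <- y - mean(y)
  freq <- seq(fmin, fmax, by = df)
  power <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau))
    st <- sin(w * (t - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
  list(freq = freq, power = power)
}

band_power <- function(psd, lo, hi) {
  keep <- psd$freq >= lo & psd$freq <= hi
  if (sum(keep) < 2L) return(0)
  pracma::trapz(psd$freq[keep], psd$power[keep])
}

#' Time- and frequency-domain HRV parameters
#'
#' Mean IBI, SDNN (sample SD), RMSSD, and normalized spectral power in the
#' low-frequency (0.04-0.15 Hz) and high-frequency (0.15-0.4 Hz) bands.
#' Normalization is over LF + HF only (the very-low-frequency content is
#' excluded); the two normalized powers sum to 100 by construction.
#'
#' @param ibi Corrected per-condition `ibi_series` (>= 2 intervals).
#' @param psd Optional precomputed PSD (list with `freq`, `power`). When
#'   `NULL`, the series is resampled at `resample_fs` and the Lomb-Scargle
#'   periodogram is used; when too short for spectral analysis the
#'   normalized powers are `NA`.
#' @param resample_fs Resampling rate for the spectral chain (default 4 Hz).
#' @return List with `mean_ibi`, `sdnn`, `rmssd` (ms) and `lf_nu`, `hf_nu`
#'   (percent).
#' @export
hrv_metrics <- function(ibi, psd = NULL, resample_fs = 4) {
  x <- ibi$intervals
  if (length(x) < 2L) stop("hrv_metrics requires >= 2 intervals")
  out <- list(
    mean_ibi = mean(x),
    sdnn = stats::sd(x),
    rmssd = sqrt(mean(diff(x)^2))
  )
  if (is.null(psd)) {
    psd <- tryCatch({
      rs <- resample_ibi(ibi, fs = resample_fs)
      lomb_scargle_psd(rs)
    }, error = function(e) NULL)
  }
  if (is.null(psd)) {
    out$lf_nu <- NA_real_
    out$hf_nu <- NA_real_
  } else {
    lf <- band_power(psd, 0.04, 0.15)
    hf <- band_power(psd, 0.15, 0.4)
    if (lf + hf <= 0) {
      out$lf_nu <- NA_real_
      out$hf_nu <- NA_real_
    } else {
      out$lf_nu <- 100 * lf / (lf + hf)
      out$hf_nu <- 100 - out$lf_nu
    }
  }
  out
}
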