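# EDA pipeline: 1-s smoothing and z-scoring, convex decomposition into a
# sparse non-negative sudomotor driver convolved with a bi-exponential
# response plus a smooth spline tonic, stationary Haar wavelet artifact
# detection on the raw signal, and the time/frequency EDA parameters.

#' Smooth and standardize an EDA recording
#'
#' Centered moving average across a 1-second window (truncated at the
#' edges), optional decimation to a common analysis rate, then z-score
#' normalization over the full recording (before any condition slicing).
#'
#' @param eda `uniform_series` in microsiemens, >= 10 s long.
#' @param target_fs Optional output rate in Hz; the high-rate gold-standard
#'   channel is decimated after smoothing (the 1-s average acts as the
#'   anti-alias filter).
#' @param window_s Smoothing window in seconds (default 1).
#' @return A z-scored `uniform_series` (attributes `center`, `scale` hold
#'   the removed mean and SD in the original units).
#' @export
preprocess_eda <- function(eda, target_fs = NULL, window_s = 1) {
  stopifnot(inherits(eda, "uniform_series"))
  if (series_duration(eda) < 10) stop("preprocess_eda requires >= 10 s of data")
  x <- running_mean(eda$values, max(1L, round(eda$fs * window_s)))
  fs <- eda$fs
  if (!is.null(target_fs) && target_fs < fs) {
    k <- round(fs / target_fs)
    x <- x[seq(1L, length(x), by = k)]
    fs <- fs / k
  }
  s <- stats::sd(x)
  if (s == 0) stop("flat EDA signal (zero variance)")
  m <- mean(x)
  out <- uniform_series((x - m) / s, fs = fs, t0 = eda$t0, units = "z")
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

# centered moving average with edge truncation (partial windows)
running_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1L) return(x)
  h <- floor(w / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Convex tonic/phasic EDA decomposition
#'
#' Models the standardized skin conductance as a sparse non-negative
#' sudomotor driver convolved with a bi-exponential impulse response
#' (time constants `tau1` rise, `tau0` decay), plus a tonic term (cubic
#' B-spline on a coarse knot grid with an affine drift), plus a residual.
#' The decomposition minimizes
#' `0.5 * ||residual||^2 + alpha * ||driver||_1 + 0.5 * gamma * ||D2 spline||^2`
#' subject to a non-negative driver, where `D2` takes second differences of
#' the spline coefficients (a P-spline roughness penalty): tonic drift of
#' any amplitude is cheap as long as it is smooth at the knot scale, while
#' SCR-speed kinks are expensive, which is what separates the components. The quadratic program is solved by
#' alternating a closed-form ridge solve for the tonic block with
#' accelerated proximal-gradient (FISTA) steps for the driver, using
#' FFT convolution.
#'
#' @param z_eda Preprocessed `uniform_series` from [preprocess_eda()].
#' @param tau0,tau1 Decay and rise time constants of the SCR impulse
#'   response, seconds (defaults 2 and 0.7).
#' @param knot_s Tonic spline knot spacing, seconds (default 10).
#' @param alpha L1 penalty on the driver (default 8e-4).
#' @param gamma Roughness penalty weight on the tonic spline (default 1).
#' @param outer_iters,fista_iters Alternation and inner iteration counts.
#' @param tol Relative objective-change convergence tolerance.
#' @param smooth_window_s The smoothing window already applied by
#'   [preprocess_eda()], seconds; the model impulse response is convolved
#'   with the same window so that the model matches the signal actually
#'   being decomposed (default 1, set 0 to disable).
#' @return An object of class `eda_decomposition`: `tonic`, `phasic`,
#'   `driver` (non-negative), `residual` (all per sample, z-units), plus
#'   `fs`, `t0`, `objective` and `converged`.
#' @export
cvxeda_decompose <- function(z_eda, tau0 = 2, tau1 = 0.7, knot_s = 10,
                             alpha = 8e-4, gamma = 1,
                             outer_iters = 12, fista_iters = 60,
                             tol = 1e-6, smooth_window_s = 1) {
  stopifnot(inherits(z_eda, "uniform_series"))
  y <- z_eda$values
  fs <- z_eda$fs
  n <- length(y)
  if (n < 8L) stop("series too short to decompose")

  # SCR impulse response, unit peak so the driver is in response-amplitude units
  tk <- (0:round(10 * tau0 * fs)) / fs
  h <- exp(-tk / tau0) - exp(-tk / tau1)
  if (smooth_window_s > 0) {
    # identical smoothing path as preprocess_eda, on a zero-padded copy so
    # the window is symmetric everywhere
    w <- max(1L, round(fs * smooth_window_s))
    hw <- floor(w / 2)
    padded <- c(rep(0, hw + 1L), h, rep(0, hw + 1L))
    h <- running_mean(padded, w)[(hw + 2L):(hw + 1L + length(h))]
  }
  h <- h / max(h)

  nfft <- stats::nextn(n + length(h), 2)
  H <- stats::fft(c(h, rep(0, nfft - length(h))))
  conv_h <- function(p) {
    Re(stats::fft(stats::fft(c(p, rep(0, nfft - n))) * H, inverse = TRUE))[1:n] / nfft
  }
  corr_h <- function(r) {
    Re(stats::fft(stats::fft(c(r, rep(0, nfft - n))) * Conj(H),
                  inverse = TRUE))[1:n] / nfft
  }
  lip <- max(Mod(H)^2)

  # tonic basis: intercept + slope + cubic B-splines on the knot grid
  tt <- (seq_len(n) - 1L) / fs
  knots <- if (max(tt) > 2 * knot_s) {
    seq(knot_s, max(tt) - knot_s, by = knot_s)
  } else {
    numeric(0)
  }
  B <- cbind(1, tt / max(tt),
             if (length(knots)) splines::bs(tt, knots = knots, degree = 3))
  ns <- ncol(B) - 2L  # spline block size (affine part unpenalized)
  P <- matrix(0, ncol(B), ncol(B))
  if (ns >= 3L) {
    D2 <- diff(diag(ns), differences = 2)
    P[-(1:2), -(1:2)] <- crossprod(D2)
  }
  BtB <- crossprod(B) + gamma * P
  ch <- chol(BtB)
  solve_tonic <- function(resid_target) {
    backsolve(ch, forwardsolve(t(ch), crossprod(B, resid_target)))
  }

  p <- rep(0, n)
  l <- solve_tonic(y)
  obj <- function(p, l) {
    r <- y - conv_h(p) - B %*% l
    0.5 * sum(r^2) + alpha * sum(p) + 0.5 * gamma * sum((P %*% l) * l)
  }
  prev <- obj(p, l)
  converged <- FALSE
  for (it in seq_len(outer_iters)) {
    # FISTA on the driver with the tonic fixed
    z <- p
    tconst <- 1
    yt <- y - as.numeric(B %*% l)
    for (k in seq_len(fista_iters)) {
      grad <- corr_h(conv_h(z) - yt)
      pn <- pmax(0, z - (grad + alpha) / lip)
      tn <- (1 + sqrt(1 + 4 * tconst^2)) / 2
      z <- pn + ((tconst - 1) / tn) * (pn - p)
      p <- pn
      tconst <- tn
    }
    l <- solve_tonic(y - conv_h(p))
    # prune sub-scale driver residue left by the slow L1 shrinkage (its
    # offset moves into the free intercept); keep only if this descends
    if (max(p) > 0) {
      p2 <- p
      p2[p2 < 0.01 * max(p2)] <- 0
      l2 <- solve_tonic(y - conv_h(p2))
      if (obj(p2, l2) <= obj(p, l)) {
        p <- p2
        l <- l2
      }
    }
    cur <- obj(p, l)
    if (!is.finite(cur)) stop("EDA decomposition did not converge (objective ",
                              "is not finite at iteration ", it, ")")
    if (abs(prev - cur) <= tol * max(1, abs(prev))) {
      converged <- TRUE
      prev <- cur
      break
    }
    prev <- cur
  }
  phasic <- conv_h(p)
  tonic <- as.numeric(B %*% l)
  structure(
    list(tonic = tonic, phasic = phasic, driver = p,
         residual = y - phasic - tonic, fs = fs, t0 = z_eda$t0,
         objective = prev, converged = converged,
         params = list(tau0 = tau0, tau1 = tau1, knot_s = knot_s,
                       alpha = alpha, gamma = gamma)),
    class = "eda_decomposition"
  )
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat(sprintf(
    "<eda_decomposition> %d samples @ %g Hz; driver L1 %.3f; residual RMSE %.4f\n",
    length(x$tonic), x$fs, sum(x$driver), sqrt(mean(x$residual^2))
  ))
  invisible(x)
}

#' Detect EDA artifacts with the stationary Haar wavelet transform
#'
#' Level-1 detail coefficients of the undecimated Haar transform respond to
#' abrupt changes such as electrode contact losses. Coefficients whose
#' magnitude exceeds `multiplier` times the centered moving average of the
#' coefficient magnitudes across a `window_s` window (truncated at the
#' recording edges) are outliers; runs of consecutive outliers, padded by
#' `pad_s`, become candidate intervals, and a candidate is kept only when
#' the raw EDA across it is not strictly monotone (a clean smooth rise or
#' fall is physiology, not an artifact).
#'
#' @param raw_eda Raw (pre-normalization) EDA `uniform_series`, full
#'   recording.
#' @param window_s Moving-average window for the outlier criterion,
#'   seconds (default 1000).
#' @param multiplier Outlier multiplier (default 3).
#' @param pad_s Padding applied to candidate intervals before the
#'   monotonicity check, seconds (default 1).
#' @return Data frame with columns `start_s`, `stop_s` (possibly 0 rows),
#'   times relative to the recording start.
#' @export
wavelet_artifact_detect <- function(raw_eda, window_s = 1000, multiplier = 3,
                                    pad_s = 1) {
  stopifnot(inherits(raw_eda, "uniform_series"))
  x <- raw_eda$values
  fs <- raw_eda$fs
  n <- length(x)
  empty <- data.frame(start_s = numeric(0), stop_s = numeric(0))
  if (n < 3L) return(empty)
  d <- c(0, diff(x)) / sqrt(2)          # level-1 stationary Haar detail
  absd <- abs(d)
  ma <- running_mean(absd, max(3L, round(window_s * fs)))
  outlier <- absd > multiplier * ma & absd > 0
  if (!any(outlier)) return(empty)

  r <- rle(outlier)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pad <- round(pad_s * fs)
  kept <- list()
  for (j in which(r$values)) {
    i0 <- max(1L, starts[j] - pad)
    i1 <- min(n, ends[j] + pad)
    seg <- x[i0:i1]
    dd <- diff(seg)
    # a clean physiological ramp is not an artifact ...
    strictly_monotone <- all(dd > 0) || all(dd < 0)
    # ... nor is an isolated noise excursion with no level change across
    # the interval (a contact loss shifts the level; same 3x scale as the
    # coefficient criterion, mapped back to raw units) ...
    pre <- x[max(1L, i0 - pad):i0]
    post <- x[i1:min(n, i1 + pad)]
    shift <- abs(stats::median(post) - stats::median(pre))
    level_change <- shift > multiplier * sqrt(2) * mean(ma[i0:i1])
    # ... nor a fast sympathetic rise: a contact loss is abrupt (the level
    # shift concentrates in essentially one sampling step) and then
    # settles on a flat shifted plateau, whereas an SCR keeps evolving
    # (decay time constant of seconds) after the candidate window
    abrupt <- length(dd) && max(abs(dd)) >= 0.5 * shift
    wp <- 2L * pad
    post_near <- x[min(n, i1):min(n, i1 + wp)]
    post_far <- x[min(n, i1 + 3L * pad):min(n, i1 + 5L * pad)]
    plateau <- abs(stats::median(post_far) - stats::median(post_near)) <
      0.25 * shift
    if (!strictly_monotone && level_change && abrupt && plateau) {
      kept[[length(kept) + 1L]] <- c((i0 - 1L) / fs, (i1 - 1L) / fs)
    }
  }
  if (!length(kept)) return(empty)
  iv <- do.call(rbind, kept)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  # merge overlaps
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

#' Time- and frequency-domain EDA parameters for one condition
#'
#' Samples inside artifact intervals are excluded from every statistic.
#' Reported values: mean retained tonic level, frequency of non-specific
#' phasic peaks (NS.EDRs, per second of retained signal), time-normalized
#' area under the non-negative phasic component, normalized spectral power
#' in the very-low (0-0.045 Hz) and low (0.045-0.15 Hz) frequency bands of
#' the phasic component (periodogram over the longest artifact-free
#' stretch), and a responsiveness flag (at least one phasic peak).
#'
#' @param decomp `eda_decomposition` for the full recording.
#' @param start_s,stop_s Condition bounds in seconds (half-open), relative
#'   to the recording start.
#' @param artifact_intervals Data frame from [wavelet_artifact_detect()]
#'   (or `NULL`).
#' @param scr_prominence Minimum phasic peak prominence in z-units
#'   (default 0.05).
#' @param min_retained_s Minimum retained duration for usable metrics
#'   (default 30 s).
#' @return List with `mean_tonic`, `ns_edrs`, `norm_auc`, `vlf_nu`,
#'   `lf_nu_eda`, `responsive`, `usable`, `retained_s`.
#' @export
eda_metrics <- function(decomp, start_s, stop_s, artifact_intervals = NULL,
                        scr_prominence = 0.05, min_retained_s = 30) {
  stopifnot(inherits(decomp, "eda_decomposition"))
  fs <- decomp$fs
  n <- length(decomp$tonic)
  t <- (seq_len(n) - 1L) / fs
  seg <- t >= start_s & t < stop_s
  art <- rep(FALSE, n)
  if (!is.null(artifact_intervals) && nrow(artifact_intervals)) {
    for (j in seq_len(nrow(artifact_intervals))) {
      art <- art | (t >= artifact_intervals$start_s[j] &
                      t <= artifact_intervals$stop_s[j])
    }
  }
  retained <- seg & !art
  ret_s <- sum(retained) / fs
  na_out <- list(mean_tonic = NA_real_, ns_edrs = NA_real_,
                 norm_auc = NA_real_, vlf_nu = NA_real_,
                 lf_nu_eda = NA_real_, responsive = NA,
                 usable = FALSE, retained_s = ret_s)
  if (ret_s < min_retained_s) return(na_out)

  phasic <- decomp$phasic
  peaks <- find_peaks(phasic, min_dist = max(1L, round(fs)),
                      min_prominence = scr_prominence)
  peaks <- peaks[retained[peaks]]
  n_scr <- length(peaks)

  # trapezoidal area over each contiguous retained run; remember the longest
  runs <- rle(retained)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  true_runs <- which(runs$values)
  auc <- 0
  for (j in true_runs) {
    idx <- starts[j]:ends[j]
    if (length(idx) > 1L) {
      auc <- auc + pracma::trapz(t[idx], pmax(phasic[idx], 0))
    }
  }
  jmax <- true_runs[which.max(runs$lengths[true_runs])]

  vlf_nu <- lf_nu <- NA_real_
  if (runs$lengths[jmax] / fs >= min_retained_s) {
    pg <- simple_periodogram(phasic[starts[jmax]:ends[jmax]], fs)
    vlf <- band_power(pg, 0, 0.045)
    lf <- band_power(pg, 0.045, 0.15)
    if (vlf + lf > 0) {
      vlf_nu <- 100 * vlf / (vlf + lf)
      lf_nu <- 100 - vlf_nu
    }
  }

  list(
    mean_tonic = mean(decomp$tonic[retained]),
    ns_edrs = n_scr / ret_s,
    norm_auc = auc / ret_s,
    vlf_nu = vlf_nu,
    lf_nu_eda = lf_nu,
    responsive = n_scr >= 1,
    usable = TRUE,
    retained_s = ret_s
  )
}
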