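# Shared fixtures: short schedules and motion-free configs keep unit tests
# fast; full-length recordings are reserved for the acceptance suite.

short_schedule <- function(eda_site = "finger") {
  default_schedule(
    eda_site = eda_site,
    durations = c(Baseline = 120, VideoClip = 120, Scream = 60,
                  NRDriving = 60, LRDriving = 60, HRDriving = 60)
  )
}

no_motion <- function() {
  list(burst_rate_per_min = c(Baseline = 0, VideoClip = 0, Scream = 0,
                              NRDriving = 0, LRDriving = 0, HRDriving = 0))
}

motion_free_config <- function(n_subjects = 1, seed = 1, ...) {
  synth_config(n_subjects = n_subjects, seed = seed,
               motion_spec = no_motion(), ...)
}

# independent R-peak oracle: threshold crossing + local argmax, used to
# check synthetic ECG round trips without relying on the package detector
naive_ecg_peaks <- function(ecg, min_sep_s = 0.3) {
  x <- ecg$values
  thr <- 0.5 * max(x)
  idx <- which(x > thr)
  if (!length(idx)) return(numeric(0))
  groups <- split(idx, cumsum(c(1, diff(idx) > min_sep_s * ecg$fs)))
  vapply(groups, function(g) (g[which.max(x[g])] - 1) / ecg$fs, numeric(1))
}

# SCR kernel of the generator, unit peak (independent re-derivation)
scr_kernel <- function(t) {
  k <- exp(-t / 4) - exp(-t / 1)
  tpk <- log(4) / (1 - 1 / 4)
  k / (exp(-tpk / 4) - exp(-tpk))
}
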