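#' Regularly sampled signal
#'
#' Container for a uniformly sampled channel (or a set of equal-length
#' channels, e.g. the three accelerometer axes). Time of sample `i` is
#' `t0 + (i - 1) / fs` seconds.
#'
#' @param values Numeric vector, or a matrix with one column per channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds (POSIX seconds or recording-relative).
#' @param units Unit label carried as metadata (e.g. "uS", "g").
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, fs, t0 = 0, units = NA_character_) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.matrix(values)) {
    stopifnot(ncol(values) >= 1L)
  } else {
    values <- as.numeric(values)
  }
  structure(
    list(values = values, fs = fs, t0 = t0, units = units),
    class = "uniform_series"
  )
}

#' @export
print.uniform_series <- function(x, ...) {
  n <- n_samples(x)
  cat(sprintf(
    "<uniform_series> %d samples @ %g Hz (%.1f s)%s\n",
    n, x$fs, n / x$fs,
    if (is.na(x$units)) "" else paste0(" [", x$units, "]")
  ))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) n_samples(x)

n_samples <- function(x) {
  if (is.matrix(x$values)) nrow(x$values) else length(x$values)
}

#' Sample times of a uniform series
#'
#' @param x A `uniform_series`.
#' @param relative If `TRUE` (default) times start at 0 rather than `t0`.
#' @return Numeric vector of sample times in seconds.
#' @export
series_time <- function(x, relative = TRUE) {
  t <- (seq_len(n_samples(x)) - 1L) / x$fs
  if (relative) t else t + x$t0
}

#' Duration of a uniform series in seconds
#' @param x A `uniform_series`.
#' @export
series_duration <- function(x) n_samples(x) / x$fs

#' Inter-beat interval series
#'
#' Event-based representation of heart beats. Each entry is a beat with the
#' interval (ms) separating it from the preceding beat. The first beat of a
#' recording carries no interval and is therefore not an entry. For a
#' contiguous stream, `interval[i]` equals
#' `(beat_time[i] - beat_time[i - 1]) * 1000`; gappy device-native streams
#' violate this at dropout boundaries, which is exactly how dropouts are
#' detected downstream.
#'
#' @param beat_times Beat times in seconds, strictly increasing.
#' @param intervals Intervals in ms, same length as `beat_times`.
#' @param flags Artifact flags, one of `"none"`, `"missing_beat"`,
#'   `"extra_beat"`, `"artifact"`, `"manual"`.
#' @return An object of class `ibi_series`.
#' @export
ibi_series <- function(beat_times, intervals,
                       flags = rep("none", length(beat_times))) {
  beat_times <- as.numeric(beat_times)
  intervals <- as.numeric(intervals)
  stopifnot(length(beat_times) == length(intervals),
            length(flags) == length(beat_times))
  if (length(beat_times) > 1L && any(diff(beat_times) <= 0)) {
    stop("beat_times must be strictly increasing")
  }
  ok <- c("none", "missing_beat", "extra_beat", "artifact", "manual")
  if (!all(flags %in% ok)) {
    stop("unknown artifact flag: ", paste(setdiff(flags, ok), collapse = ", "))
  }
  structure(
    list(beat_times = beat_times, intervals = intervals,
         flags = as.character(flags)),
    class = "ibi_series"
  )
}

#' Build an IBI series from a vector of beat times
#'
#' @param beat_times Strictly increasing beat times in seconds (>= 2 beats
#'   for a non-empty result).
#' @return An `ibi_series` with one entry per beat from the second onwards.
#' @export
ibi_from_beats <- function(beat_times) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2L) {
    return(ibi_series(numeric(0), numeric(0), character(0)))
  }
  ibi_series(beat_times[-1L], diff(beat_times) * 1000)
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d intervals", length(x$beat_times)))
  if (length(x$beat_times)) {
    cat(sprintf(", mean %.1f ms, %d flagged",
                mean(x$intervals), sum(x$flags != "none")))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.ibi_series <- function(x) length(x$beat_times)

#' Condition schedule
#'
#' Ordered, non-overlapping labeled intervals describing the experimental
#' protocol, plus the gold-standard EDA recording site.
#'
#' @param labels Condition labels (from [condition_labels()]).
#' @param start_s,stop_s Interval bounds in seconds; intervals are half-open
#'   `[start, stop)`.
#' @param eda_site Gold-standard EDA site, `"finger"` or `"shoulder"`.
#' @return An object of class `condition_schedule`.
#' @export
condition_schedule <- function(labels, start_s, stop_s, eda_site = "finger") {
  stopifnot(length(labels) == length(start_s),
            length(start_s) == length(stop_s),
            eda_site %in% c("finger", "shoulder"))
  if (!all(labels %in% condition_labels())) {
    stop("unknown condition label: ",
         paste(setdiff(labels, condition_labels()), collapse = ", "))
  }
  o <- order(start_s)
  labels <- labels[o]; start_s <- start_s[o]; stop_s <- stop_s[o]
  if (any(stop_s <= start_s)) stop("schedule entries must have stop > start")
  if (length(start_s) > 1L && any(start_s[-1L] < stop_s[-length(stop_s)])) {
    stop("schedule entries must not overlap")
  }
  structure(
    list(entries = data.frame(label = labels, start_s = start_s,
                              stop_s = stop_s, stringsAsFactors = FALSE),
         eda_site = eda_site),
    class = "condition_schedule"
  )
}

#' The six experimental condition labels, in protocol order
#' @export
condition_labels <- function() {
  c("Baseline", "VideoClip", "Scream", "NRDriving", "LRDriving", "HRDriving")
}

#' Default condition schedule
#'
#' Baseline 180 s, Video Clip 720 s, Scream 150 s and three driving videos of
#' 210 s each, back to back.
#'
#' @param eda_site Gold-standard EDA site.
#' @param durations Named vector of per-condition durations in seconds,
#'   overriding the defaults.
#' @return A `condition_schedule`.
#' @export
default_schedule <- function(eda_site = "finger", durations = NULL) {
  d <- c(Baseline = 180, VideoClip = 720, Scream = 150,
         NRDriving = 210, LRDriving = 210, HRDriving = 210)
  if (!is.null(durations)) d[names(durations)] <- durations
  if (any(d <= 0)) stop("all condition durations must be > 0")
  stop_s <- cumsum(as.numeric(d))
  condition_schedule(names(d), c(0, stop_s[-length(stop_s)]), stop_s,
                     eda_site = eda_site)
}

#' @export
print.condition_schedule <- function(x, ...) {
  cat(sprintf("<condition_schedule> %d entries, EDA site %s\n",
              nrow(x$entries), x$eda_site))
  print(x$entries)
  invisible(x)
}

schedule_span <- function(schedule) {
  c(min(schedule$entries$start_s), max(schedule$entries$stop_s))
}

#' Slice a signal or beat series by experimental condition
#'
#' Splits the input into one segment per schedule entry using half-open
#' `[start, stop)` intervals; beats are assigned by beat time. Times are
#' interpreted relative to the start of the recording.
#'
#' @param x A `uniform_series` or `ibi_series`.
#' @param schedule A `condition_schedule`.
#' @return A named list of segments (names are condition labels).
#' @export
slice_by_condition <- function(x, schedule) {
  UseMethod("slice_by_condition")
}

#' @export
slice_by_condition.uniform_series <- function(x, schedule) {
  t <- series_time(x)
  dur <- series_duration(x)
  if (max(schedule$entries$stop_s) > dur + 1 / x$fs + 1e-9) {
    stop("schedule exceeds series span")
  }
  out <- lapply(seq_len(nrow(schedule$entries)), function(i) {
    e <- schedule$entries[i, ]
    keep <- t >= e$start_s & t < e$stop_s
    v <- if (is.matrix(x$values)) x$values[keep, , drop = FALSE] else x$values[keep]
    uniform_series(v, x$fs, t0 = x$t0 + e$start_s, units = x$units)
  })
  names(out) <- schedule$entries$label
  out
}

#' @export
slice_by_condition.ibi_series <- function(x, schedule) {
  out <- lapply(seq_len(nrow(schedule$entries)), function(i) {
    e <- schedule$entries[i, ]
    keep <- x$beat_times >= e$start_s & x$beat_times < e$stop_s
    ibi_series(x$beat_times[keep], x$intervals[keep], x$flags[keep])
  })
  names(out) <- schedule$entries$label
  out
}
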