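# Wearable export dialect:
#   BVP.csv / EDA.csv : row 1 = UTC start timestamp, row 2 = sampling rate,
#                       rows 3+ = samples (one column).
#   ACC.csv           : same layout with 3 columns; samples are raw counts,
#                       64 counts = 1 g (derived from the +-2 g range).
#   IBI.csv           : row 1 = start timestamp (+ literal "IBI" tag),
#                       rows 2+ = (seconds offset of beat, interval in s).
# Gold-standard CSV:  row 1 = channel names, row 2 = per-channel sampling
#                       rate, rows 3+ = samples.

ACC_COUNTS_PER_G <- 64

#' Read a wearable-device CSV export directory
#'
#' Expects `BVP.csv`, `EDA.csv`, `ACC.csv` and `IBI.csv` in the device
#' export dialect (start timestamp, sampling rate, then samples; see
#' package vignette). Accelerometer counts are converted to g.
#'
#' @param directory Path to the export directory.
#' @return A list with `bvp`, `eda`, `accel` (`uniform_series`) and
#'   `native_ibi` (`ibi_series`).
#' @export
read_device_export <- function(directory) {
  need <- c("BVP.csv", "EDA.csv", "ACC.csv", "IBI.csv")
  missing <- need[!file.exists(file.path(directory, need))]
  if (length(missing)) {
    stop("missing device stream file(s): ", paste(missing, collapse = ", "))
  }
  bvp <- read_e4_signal(file.path(directory, "BVP.csv"))
  eda <- read_e4_signal(file.path(directory, "EDA.csv"), units = "uS")
  acc <- read_e4_signal(file.path(directory, "ACC.csv"), units = "g")
  acc$values <- acc$values / ACC_COUNTS_PER_G
  list(
    bvp = bvp,
    eda = eda,
    accel = acc,
    native_ibi = read_e4_ibi(file.path(directory, "IBI.csv"))
  )
}

read_e4_signal <- function(path, units = NA_character_) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed header in ", path, " (line 1)")
  t0 <- suppressWarnings(as.numeric(strsplit(lines[1L], ",")[[1L]][1L]))
  fs <- suppressWarnings(as.numeric(strsplit(lines[2L], ",")[[1L]][1L]))
  if (is.na(t0)) stop("malformed header in ", path, " (line 1)")
  if (is.na(fs) || fs <= 0) stop("malformed header in ", path, " (line 2)")
  if (length(lines) > 2L) {
    body <- do.call(rbind, lapply(seq_along(lines[-(1:2)]) + 2L, function(i) {
      v <- suppressWarnings(as.numeric(strsplit(lines[i], ",")[[1L]]))
      if (anyNA(v)) stop("parse error in ", path, " at line ", i)
      v
    }))
    vals <- if (ncol(body) == 1L) body[, 1L] else body
  } else {
    vals <- numeric(0)
  }
  uniform_series(vals, fs = fs, t0 = t0, units = units)
}

read_e4_ibi <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("malformed header in ", path, " (line 1)")
  if (length(lines) == 1L) {
    return(ibi_series(numeric(0), numeric(0), character(0)))
  }
  body <- do.call(rbind, lapply(seq_along(lines[-1L]) + 1L, function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], ",")[[1L]]))
    if (length(v) != 2L || anyNA(v)) {
      stop("parse error in ", path, " at line ", i)
    }
    v
  }))
  ibi_series(beat_times = body[, 1L], intervals = body[, 2L] * 1000)
}

#' Write a recording in the wearable-device export dialect
#'
#' Inverse of [read_device_export()]; round-trips are value-exact (the
#' counts-per-g factor is a power of two).
#'
#' @param streams List with `bvp`, `eda`, `accel`, `native_ibi` as returned
#'   by [read_device_export()] or built by the synthetic generator.
#' @param directory Output directory (created if needed).
#' @export
write_device_export <- function(streams, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_e4_signal(streams$bvp, file.path(directory, "BVP.csv"))
  write_e4_signal(streams$eda, file.path(directory, "EDA.csv"))
  acc <- streams$accel
  acc$values <- acc$values * ACC_COUNTS_PER_G
  write_e4_signal(acc, file.path(directory, "ACC.csv"))
  ibi <- streams$native_ibi
  lines <- c(
    sprintf("%s, IBI", num_chr(ibi_t0(streams))),
    sprintf("%s,%s", num_chr(ibi$beat_times), num_chr(ibi$intervals / 1000))
  )
  writeLines(lines, file.path(directory, "IBI.csv"))
  invisible(directory)
}

ibi_t0 <- function(streams) streams$bvp$t0

write_e4_signal <- function(x, path) {
  vals <- if (is.matrix(x$values)) x$values else matrix(x$values, ncol = 1L)
  k <- ncol(vals)
  lines <- c(
    paste(rep(num_chr(x$t0), k), collapse = ","),
    paste(rep(num_chr(x$fs), k), collapse = ","),
    apply(vals, 1L, function(r) paste(num_chr(r), collapse = ","))
  )
  writeLines(lines, path)
}

# full-precision numeric formatting so write -> read round-trips exactly
num_chr <- function(x) sprintf("%.17g", x)

#' Read a gold-standard recording CSV
#'
#' One column per channel; row 1 names the channels (`ECG`, `EDA`), row 2
#' gives each channel's sampling rate, remaining rows are samples.
#'
#' @param file Path to the CSV.
#' @return A list of `uniform_series`, named by lower-case channel.
#' @export
read_gold_standard <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 2L) stop("malformed gold-standard header")
  channels <- trimws(strsplit(lines[1L], ",")[[1L]])
  known <- c("ECG", "EDA")
  bad <- setdiff(channels, known)
  if (length(bad)) stop("unknown gold-standard channel: ", bad[1L])
  fs <- suppressWarnings(as.numeric(strsplit(lines[2L], ",")[[1L]]))
  if (length(fs) != length(channels) || anyNA(fs) || any(fs <= 0)) {
    stop("gold-standard sampling-rate row does not match channel header")
  }
  body <- if (length(lines) > 2L) {
    do.call(rbind, strsplit(lines[-(1:2)], ","))
  } else {
    matrix(character(0), ncol = length(channels))
  }
  out <- lapply(seq_along(channels), function(j) {
    units <- if (channels[j] == "EDA") "uS" else NA_character_
    uniform_series(as.numeric(body[, j]), fs = fs[j], units = units)
  })
  names(out) <- tolower(channels)
  out
}

#' Write a gold-standard recording CSV
#'
#' @param ecg,eda `uniform_series` for the two channels (equal durations
#'   and sampling rates expected for a paired file).
#' @param file Output path.
#' @export
write_gold_standard <- function(ecg, eda, file) {
  stopifnot(n_samples(ecg) == n_samples(eda))
  lines <- c(
    "ECG,EDA",
    paste(num_chr(c(ecg$fs, eda$fs)), collapse = ","),
    paste(num_chr(ecg$values), num_chr(eda$values), sep = ",")
  )
  writeLines(lines, file)
  invisible(file)
}

#' Read / write a condition schedule as JSON
#' @param file JSON path.
#' @return A `condition_schedule`.
#' @export
read_schedule <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  condition_schedule(x$entries$label, x$entries$start_s, x$entries$stop_s,
                     eda_site = x$eda_site)
}

#' @rdname read_schedule
#' @param schedule A `condition_schedule`.
#' @export
write_schedule <- function(schedule, file) {
  jsonlite::write_json(
    list(eda_site = schedule$eda_site, entries = schedule$entries),
    file, auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}

#' Read / write synthetic-recording ground truth as JSON
#' @param file JSON path.
#' @export
read_ground_truth <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}

#' @rdname read_ground_truth
#' @param truth Ground-truth list from the synthetic generator.
#' @export
write_ground_truth <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read / write the tidy metric table
#'
#' Long-format table with columns `subject`, `condition`, `device`,
#' `parameter`, `value` — one row per computed HRV/EDA parameter.
#'
#' @param file CSV path.
#' @export
read_metric_table <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' @rdname read_metric_table
#' @param metrics Metric table data frame.
#' @export
write_metric_table <- function(metrics, file) {
  utils::write.csv(metrics, file, row.names = FALSE)
  invisible(file)
}
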