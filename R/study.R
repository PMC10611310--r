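# End-to-end study orchestration: run both device pipelines per subject and
# condition, assemble the tidy metric table, and compute the quality and
# agreement statistics. Subjects failing a signal family are excluded from
# that family only, with the reason recorded.

HRV_PARAMS <- c("mean_ibi", "sdnn", "rmssd", "lf_nu", "hf_nu")
EDA_PARAMS <- c("mean_tonic", "ns_edrs", "norm_auc", "vlf_nu", "lf_nu_eda")

#' Run both HRV pipelines for one subject
#'
#' ECG path: Pan-Tompkins R peaks, Berntson artifact correction. BVP path:
#' acceleration conditioning, artifact-free segment mining from the native
#' IBI stream, subject band by PSD subtraction, foot-point reconstruction,
#' Berntson correction. Both paths yield per-condition HRV metrics plus the
#' beat/artifact counts for the quality report.
#'
#' @param device,gold,schedule One subject's streams (see
#'   [simulate_subject()] / [read_device_export()]).
#' @param min_run Minimum artifact-free run length (intervals).
#' @param berntson_multiplier Criterion multiplier for artifact flagging.
#' @return List with `metrics` (long data frame), `quality` (per-condition
#'   counts and rates) and the corrected `ibi` series per path.
#' @export
process_subject_hrv <- function(device, gold, schedule, min_run = 10,
                                berntson_multiplier = 4) {
  # ECG (gold standard) path
  ibi_ecg <- detect_r_peaks(gold$ecg)
  flags_ecg <- berntson_detect(ibi_ecg, multiplier = berntson_multiplier)
  ecg_corr <- correct_artifacts(ibi_ecg, flags_ecg)

  # BVP (device) path
  mag <- accel_magnitude(device$accel)
  segs <- find_artifact_free_segments(device$native_ibi, min_run = min_run)
  spec <- if (nrow(segs)) {
    suppressWarnings(
      subject_band_from_psd_subtraction(device$bvp, mag, segs)
    )
  } else {
    filter_spec(0.5, 3)
  }
  ibi_bvp <- reconstruct_bvp_ibi(device$bvp, spec)
  flags_bvp <- berntson_detect(ibi_bvp, multiplier = berntson_multiplier)
  bvp_corr <- correct_artifacts(ibi_bvp, flags_bvp)

  per_device <- list(gold = ecg_corr, device = bvp_corr)
  rows <- list()
  qual <- list()
  for (dev in names(per_device)) {
    slices <- slice_by_condition(per_device[[dev]], schedule)
    for (cond in names(slices)) {
      sl <- slices[[cond]]
      if (length(sl) < 2L) next
      m <- hrv_metrics(sl)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, device = dev, parameter = HRV_PARAMS,
        value = unlist(m[HRV_PARAMS], use.names = FALSE)
      )
      qual[[length(qual) + 1L]] <- data.frame(
        condition = cond, device = dev, n_beats = length(sl),
        n_artifacts = sum(sl$flags != "none")
      )
    }
  }
  list(
    metrics = do.call(rbind, rows),
    quality = do.call(rbind, qual),
    native_capture = 100 * length(device$native_ibi) / max(1L, length(ibi_ecg)),
    filter_spec = spec,
    ibi = per_device
  )
}

#' Run the EDA pipeline for one system
#'
#' 1-s smoothing, decimation to the common analysis rate, z-scoring, convex
#' tonic/phasic decomposition, stationary Haar artifact detection on the
#' raw signal, per-condition metrics.
#'
#' @param eda Raw EDA `uniform_series`.
#' @param schedule `condition_schedule`.
#' @param analysis_fs Common decomposition rate, default 4 Hz.
#' @param ... Passed to [cvxeda_decompose()].
#' @return List with `metrics` (long data frame, parameter/condition),
#'   `responsive` per condition, `artifacts`, and the decomposition.
#' @export
process_subject_eda <- function(eda, schedule, analysis_fs = 4, ...) {
  z <- preprocess_eda(eda, target_fs = analysis_fs)
  # artifact detection runs at the common analysis rate for both systems;
  # plain subsampling keeps contact-loss steps instantaneous
  raw <- eda
  if (eda$fs > analysis_fs) {
    k <- round(eda$fs / analysis_fs)
    raw <- uniform_series(eda$values[seq(1L, length(eda$values), by = k)],
                          fs = eda$fs / k, t0 = eda$t0, units = eda$units)
  }
  artifacts <- wavelet_artifact_detect(raw)
  decomp <- cvxeda_decompose(z, ...)
  rows <- list()
  resp <- list()
  for (i in seq_len(nrow(schedule$entries))) {
    e <- schedule$entries[i, ]
    m <- eda_metrics(decomp, e$start_s, e$stop_s, artifacts)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = e$label, parameter = EDA_PARAMS,
      value = unlist(m[EDA_PARAMS], use.names = FALSE)
    )
    resp[[length(resp) + 1L]] <- data.frame(
      condition = e$label, responsive = isTRUE(m$responsive),
      usable = m$usable
    )
  }
  list(metrics = do.call(rbind, rows), responsiveness = do.call(rbind, resp),
       artifacts = artifacts, decomposition = decomp)
}

#' Run the complete validation study
#'
#' Simulates (or accepts) a cohort of paired recordings, runs the ECG/BVP
#' HRV pipelines and the EDA pipeline for both systems, and computes the
#' quality report, the per-parameter agreement statistics and the Friedman
#' tests on scaled absolute errors. Subjects failing one signal family are
#' excluded from that family only.
#'
#' @param config A `synth_config` (used to simulate when `cohort` is NULL).
#' @param cohort Optional pre-built cohort (list of subject recordings).
#' @param exact_friedman Use the exact permutation Friedman p for small
#'   designs.
#' @return An object of class `study_result`: `metrics`, `quality`,
#'   `agreement`, `friedman`, `exclusions`, `config`.
#' @export
run_study <- function(config = synth_config(), cohort = NULL,
                      exact_friedman = FALSE) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  subjects <- names(cohort)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_along(cohort))

  metrics <- list()
  quality <- list()
  native <- list()
  responsiveness <- list()
  exclusions <- list()

  for (si in seq_along(cohort)) {
    sub <- cohort[[si]]
    id <- subjects[si]
    hrv <- tryCatch(
      process_subject_hrv(sub$device, sub$gold, sub$schedule),
      error = function(e) e
    )
    if (inherits(hrv, "error")) {
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(subject = id, family = "hrv",
                   reason = conditionMessage(hrv))
    } else {
      metrics[[length(metrics) + 1L]] <- cbind(subject = id, hrv$metrics)
      quality[[length(quality) + 1L]] <- cbind(subject = id, hrv$quality)
      native[[length(native) + 1L]] <-
        data.frame(subject = id, native_capture = hrv$native_capture)
    }
    for (sys in c("device", "gold")) {
      eda_in <- if (sys == "device") sub$device$eda else sub$gold$eda
      eda <- tryCatch(
        process_subject_eda(eda_in, sub$schedule),
        error = function(e) e
      )
      if (inherits(eda, "error")) {
        exclusions[[length(exclusions) + 1L]] <-
          data.frame(subject = id, family = paste0("eda_", sys),
                     reason = conditionMessage(eda))
      } else {
        metrics[[length(metrics) + 1L]] <-
          cbind(subject = id, device = sys, eda$metrics)
        responsiveness[[length(responsiveness) + 1L]] <-
          cbind(subject = id, system = sys, eda$responsiveness)
      }
    }
  }

  metrics <- if (length(metrics)) {
    do.call(rbind, lapply(metrics, function(d) {
      d[, c("subject", "condition", "device", "parameter", "value")]
    }))
  } else {
    data.frame(subject = character(0), condition = character(0),
               device = character(0), parameter = character(0),
               value = numeric(0))
  }
  quality <- do.call(rbind, quality)
  native <- do.call(rbind, native)
  responsiveness <- if (length(responsiveness)) {
    do.call(rbind, responsiveness)
  } else {
    NULL
  }

  structure(
    list(
      metrics = metrics,
      quality = quality_report(quality, native, responsiveness),
      agreement = agreement_table(metrics),
      friedman = friedman_table(metrics, exact = exact_friedman),
      exclusions = if (length(exclusions)) do.call(rbind, exclusions) else NULL,
      config = config
    ),
    class = "study_result"
  )
}

quality_report <- function(quality, native, responsiveness) {
  out <- list(native_capture = native)
  if (!is.null(quality) && nrow(quality)) {
    # Detection Rate: device vs gold beat counts per subject x condition
    dev <- quality[quality$device == "device", ]
    gs <- quality[quality$device == "gold", ]
    key <- merge(dev, gs, by = c("subject", "condition"),
                 suffixes = c("_dev", "_gs"))
    key$detection_rate <- detection_rate(key$n_beats_dev, key$n_beats_gs)
    out$detection <- key[, c("subject", "condition", "n_beats_dev",
                             "n_beats_gs", "detection_rate")]
    quality$artifact_rate <- artifact_rate(quality$n_artifacts,
                                           quality$n_beats)
    out$artifact <- quality
    agg <- stats::aggregate(detection_rate ~ condition, key, function(v) {
      c(mean = mean(v), sd = stats::sd(v))
    })
    out$detection_by_condition <- data.frame(
      condition = agg$condition,
      mean = agg$detection_rate[, "mean"],
      sd = agg$detection_rate[, "sd"]
    )
  }
  if (!is.null(responsiveness)) {
    agg <- stats::aggregate(responsive ~ system + condition, responsiveness,
                            function(v) 100 * mean(!v))
    names(agg)[3L] <- "nonresponsive_pct"
    out$nonresponsive <- agg
  }
  out
}

agreement_table <- function(metrics) {
  if (!nrow(metrics)) return(NULL)
  rows <- list()
  for (param in unique(metrics$parameter)) {
    for (cond in unique(metrics$condition)) {
      sub <- metrics[metrics$parameter == param & metrics$condition == cond, ]
      dev <- sub[sub$device == "device", c("subject", "value")]
      gs <- sub[sub$device == "gold", c("subject", "value")]
      pair <- merge(dev, gs, by = "subject", suffixes = c("_dev", "_gs"))
      pair <- pair[stats::complete.cases(pair), ]
      if (nrow(pair) < 5L) next
      sp <- spearman_ranked(pair$value_dev, pair$value_gs)
      ba <- bland_altman(pair$value_dev, pair$value_gs)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = param, condition = cond, n = nrow(pair),
        rho = sp$rho, rho_p = sp$p, ranking = sp$ranking,
        bias = ba$bias, bias_ci_halfwidth = ba$bias_ci_halfwidth,
        bias_p = ba$bias_p, loa_upper = ba$loa_upper,
        loa_lower = ba$loa_lower, loa_transformed = ba$loa_transformed
      )
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

friedman_table <- function(metrics, exact = FALSE) {
  if (!nrow(metrics)) return(NULL)
  out <- list()
  for (param in intersect(HRV_PARAMS, unique(metrics$parameter))) {
    sub <- metrics[metrics$parameter == param, ]
    dev <- sub[sub$device == "device", ]
    gs <- sub[sub$device == "gold", ]
    pair <- merge(dev, gs, by = c("subject", "condition"),
                  suffixes = c("_dev", "_gs"))
    pair <- pair[stats::complete.cases(pair[, c("value_dev", "value_gs")]), ]
    if (!nrow(pair)) next
    # full scale: range of the Bland-Altman mean axis over all cells
    fullscale <- diff(range((pair$value_dev + pair$value_gs) / 2))
    if (fullscale <= 0) next
    pair$err <- scaled_absolute_error(pair$value_dev, pair$value_gs, fullscale)
    wide <- stats::reshape(pair[, c("subject", "condition", "err")],
                           idvar = "subject", timevar = "condition",
                           direction = "wide")
    mat <- as.matrix(wide[, -1L, drop = FALSE])
    colnames(mat) <- sub("^err\\.", "", colnames(mat))
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
    if (nrow(mat) < 2L || ncol(mat) < 2L) next
    fr <- friedman_with_posthoc(mat, exact = exact)
    fr$full_scale <- fullscale
    out[[param]] <- fr
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  cat(sprintf("  metric rows: %d\n", nrow(x$metrics)))
  if (!is.null(x$agreement)) {
    cat(sprintf("  agreement rows: %d\n", nrow(x$agreement)))
  }
  if (!is.null(x$exclusions)) {
    cat(sprintf("  exclusions: %d\n", nrow(x$exclusions)))
  }
  invisible(x)
}

#' Write the study report bundle
#'
#' Writes the tidy metric table, the quality tables, the agreement table and
#' the Friedman summaries as CSV/JSON files.
#'
#' @param study A `study_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
validation_report <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metric_table(study$metrics, file.path(dir, "metrics.csv"))
  if (!is.null(study$agreement)) {
    utils::write.csv(study$agreement, file.path(dir, "agreement.csv"),
                     row.names = FALSE)
  }
  q <- study$quality
  for (nm in names(q)) {
    if (is.data.frame(q[[nm]])) {
      utils::write.csv(q[[nm]], file.path(dir, paste0("quality_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  fr <- lapply(study$friedman, function(f) {
    list(chi_squared = f$chi_squared, df = f$df, p = f$p,
         decision = f$decision, full_scale = f$full_scale,
         posthoc = f$posthoc)
  })
  jsonlite::write_json(fr, file.path(dir, "friedman.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(study$exclusions)) {
    utils::write.csv(study$exclusions, file.path(dir, "exclusions.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
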