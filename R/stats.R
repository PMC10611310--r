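# Device-agreement and quality statistics: detection and artifact rates,
# Spearman correlation with ranking bands, Bland-Altman agreement with bias
# significance and limits of agreement, Friedman tests with post hoc
# pairwise comparisons, scaled absolute errors, and the Shapiro-Wilk
# normality gate.

#' Beat detection rate
#'
#' `100 * (1 - |n_device - n_gold| / n_gold)` percent: the agreement between
#' the device and gold-standard beat counts, symmetric in the magnitude of
#' the count mismatch.
#'
#' @param n_device,n_gold Beat counts (gold count > 0).
#' @return Percentage.
#' @export
detection_rate <- function(n_device, n_gold) {
  if (any(n_gold <= 0)) stop("gold-standard beat count must be > 0")
  100 * (1 - abs(n_device - n_gold) / n_gold)
}

#' Artifact rate
#'
#' Percentage of detected beats flagged as artifacts.
#'
#' @param n_artifacts,n_beats Counts (`n_beats > 0`).
#' @return Percentage.
#' @export
artifact_rate <- function(n_artifacts, n_beats) {
  if (any(n_beats <= 0)) stop("beat count must be > 0")
  100 * n_artifacts / n_beats
}

#' Absolute error scaled to a parameter's full scale
#'
#' @param device_value,gold_value Paired metric values.
#' @param full_scale Full scale of the parameter (> 0), e.g. the range of
#'   the Bland-Altman mean axis across subjects and conditions.
#' @return Percentage.
#' @export
scaled_absolute_error <- function(device_value, gold_value, full_scale) {
  if (any(full_scale <= 0)) stop("full_scale must be > 0")
  100 * abs(device_value - gold_value) / full_scale
}

#' Spearman correlation with reliability ranking
#'
#' Tie-corrected rank correlation with a two-sided p-value and a
#' reliability band: `"high"` for rho > 0.9, `"moderate"` for
#' 0.7 <= rho <= 0.9, `"low"` for rho < 0.7, and `"none"` when the
#' correlation is not significant at the 5% level (or undefined).
#'
#' @param x,y Paired values, n >= 5.
#' @return List with `rho`, `p`, `ranking`.
#' @export
spearman_ranked <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("spearman_ranked requires n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, ranking = "none"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided",
                    exact = FALSE)
  )
  rho <- unname(ct$estimate)
  p <- ct$p.value
  ranking <- if (!is.finite(p) || p >= 0.05) {
    "none"
  } else if (rho > 0.9) {
    "high"
  } else if (rho >= 0.7) {
    "moderate"
  } else {
    "low"
  }
  list(rho = rho, p = p, ranking = ranking)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as device minus gold standard. Reports the mean
#' bias, its 95% confidence half-width (Student t, n - 1 df), the two-sided
#' p-value of the zero-bias hypothesis, and the 95% limits of agreement
#' `bias +- 1.96 * SD`. When the differences trend significantly with the
#' pair means (slope p < 0.05), regression-based limits are also computed:
#' the bias becomes a fitted line in the mean and the limits follow it at
#' `+- 1.96` residual SDs.
#'
#' @param device,gold Paired parameter values, n >= 5.
#' @return An object of class `agreement_result`.
#' @export
bland_altman <- function(device, gold) {
  stopifnot(length(device) == length(gold))
  n <- length(device)
  if (n < 5L) stop("bland_altman requires n >= 5")
  d <- device - gold
  m <- (device + gold) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  tcrit <- stats::qt(0.975, n - 1)
  ci_half <- tcrit * s / sqrt(n)
  bias_p <- if (degenerate) NaN else stats::t.test(d)$p.value

  trend <- list(slope = NA_real_, intercept = NA_real_, p = NA_real_,
                resid_sd = NA_real_)
  loa_transformed <- FALSE
  if (!degenerate && stats::sd(m) > 0) {
    fit <- stats::lm(d ~ m)
    sm <- summary(fit)$coefficients
    trend$slope <- sm[2L, 1L]
    trend$intercept <- sm[1L, 1L]
    trend$p <- sm[2L, 4L]
    trend$resid_sd <- summary(fit)$sigma
    loa_transformed <- is.finite(trend$p) && trend$p < 0.05
  }

  structure(
    list(n = n, bias = bias, sd_diff = s, bias_ci_halfwidth = ci_half,
         bias_p = bias_p, loa_upper = bias + 1.96 * s,
         loa_lower = bias - 1.96 * s, degenerate = degenerate,
         loa_transformed = loa_transformed, trend = trend),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> n=%d bias=%.3f (CI +-%.3f, p=%.3g) LOA [%.3f, %.3f]%s\n",
    x$n, x$bias, x$bias_ci_halfwidth, x$bias_p, x$loa_lower, x$loa_upper,
    if (x$loa_transformed) " [trend-adjusted limits available]" else ""
  ))
  invisible(x)
}

#' Friedman test with post hoc pairwise comparisons
#'
#' Tie-corrected Friedman chi-squared on a complete subjects-by-conditions
#' block design, with the 5% decision rule. When significant, all pairwise
#' condition comparisons are performed: either Dunn-type rank-sum z tests
#' (default, the convention of mainstream statistical suites) or paired
#' Wilcoxon signed-rank tests, Bonferroni-adjusted. For small designs an
#' exact p-value by exhaustive enumeration of within-subject rank
#' permutations is available.
#'
#' @param errors Numeric matrix, subjects in rows, conditions in columns,
#'   no missing cells.
#' @param posthoc `"dunn"` or `"wilcoxon"`.
#' @param exact Use the exact permutation distribution of the chi-squared
#'   statistic (only feasible for `factorial(k)^n` up to ~1e6).
#' @return An object of class `friedman_result` with `chi_squared`, `df`,
#'   `p`, `decision` and (when significant) a `posthoc` data frame of
#'   adjusted pairwise p-values.
#' @export
friedman_with_posthoc <- function(errors, posthoc = c("dunn", "wilcoxon"),
                                  exact = FALSE) {
  posthoc <- match.arg(posthoc)
  errors <- as.matrix(errors)
  if (anyNA(errors)) stop("complete block design required (missing cells)")
  n <- nrow(errors)
  k <- ncol(errors)
  stopifnot(n >= 2L, k >= 2L)

  chi <- friedman_chi_squared(errors)
  df <- k - 1L
  p <- if (exact) {
    exact_friedman_p(errors, chi)
  } else {
    stats::pchisq(chi, df, lower.tail = FALSE)
  }
  decision <- if (is.finite(p) && p < 0.05) "reject H0" else "maintain H0"

  ph <- NULL
  if (decision == "reject H0") {
    pairs <- utils::combn(k, 2)
    labs <- colnames(errors)
    if (is.null(labs)) labs <- paste0("C", seq_len(k))
    R <- t(apply(errors, 1L, rank))
    rbar <- colMeans(R)
    se <- sqrt(k * (k + 1) / (6 * n))
    praw <- apply(pairs, 2L, function(ij) {
      if (posthoc == "dunn") {
        z <- (rbar[ij[1L]] - rbar[ij[2L]]) / se
        2 * stats::pnorm(-abs(z))
      } else {
        suppressWarnings(stats::wilcox.test(errors[, ij[1L]], errors[, ij[2L]],
                                            paired = TRUE, exact = FALSE)$p.value)
      }
    })
    ph <- data.frame(
      condition_a = labs[pairs[1L, ]],
      condition_b = labs[pairs[2L, ]],
      p_adjusted = pmin(1, praw * ncol(pairs))
    )
  }
  structure(
    list(chi_squared = chi, df = df, p = p, decision = decision,
         posthoc = ph, method = posthoc, exact = exact),
    class = "friedman_result"
  )
}

# tie-corrected Friedman statistic (matches stats::friedman.test)
friedman_chi_squared <- function(errors) {
  n <- nrow(errors)
  k <- ncol(errors)
  R <- t(apply(errors, 1L, rank))
  colsum <- colSums(R)
  A <- sum(R^2)
  C <- n * k * (k + 1)^2 / 4
  if (A == C) return(0)  # every row fully tied: no information, chi2 = 0
  (k - 1) * (sum(colsum^2) - n^2 * k * (k + 1)^2 / 4) / (A - C)
}

exact_friedman_p <- function(errors, observed) {
  n <- nrow(errors)
  k <- ncol(errors)
  perms <- perms_of(k)
  if (nrow(perms)^n > 2e6) stop("exact enumeration infeasible for this size")
  idx <- rep(1L, n)
  total <- nrow(perms)^n
  count <- 0L
  E <- errors
  repeat {
    for (i in seq_len(n)) E[i, ] <- errors[i, perms[idx[i], ]]
    if (friedman_chi_squared(E) >= observed - 1e-12) count <- count + 1L
    j <- 1L
    while (j <= n) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= nrow(perms)) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > n) break
  }
  count / total
}

perms_of <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- perms_of(k - 1L)
  out <- matrix(0L, nrow = factorial(k), ncol = k)
  r <- 1L
  for (i in seq_len(k)) {
    for (s in seq_len(nrow(sub))) {
      row <- append(sub[s, ], k, after = i - 1L)
      out[r, ] <- row
      r <- r + 1L
    }
  }
  out
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("<friedman_result> chi2(%d) = %.3f, p = %.4g -> %s\n",
              x$df, x$chi_squared, x$p, x$decision))
  if (!is.null(x$posthoc)) {
    cat("post hoc (", x$method, ", Bonferroni):\n", sep = "")
    print(x$posthoc)
  }
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Used to justify the nonparametric choices in the validation report; it
#' does not branch the pipeline.
#'
#' @param values Sample of size 3 to 50.
#' @return List with `W`, `p` and `normal` (`p >= 0.05`).
#' @export
normality_gate <- function(values) {
  n <- length(values)
  if (n < 3L || n > 50L) stop("normality_gate requires 3 <= n <= 50")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, normal = sw$p.value >= 0.05)
}
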