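test_that("detection and artifact rates follow their defining formulas", {
  expect_equal(detection_rate(100, 100), 100)
  expect_equal(detection_rate(165, 166), 100 * (1 - 1 / 166))
  expect_equal(detection_rate(165, 166), 99.40, tolerance = 1e-2)
  expect_equal(detection_rate(0, 100), 0)
  expect_error(detection_rate(10, 0))

  # symmetric in the magnitude of the count mismatch
  for (k in c(1, 5, 20)) {
    expect_equal(detection_rate(100 + k, 100), detection_rate(100 - k, 100))
  }

  expect_equal(artifact_rate(0, 200), 0)
  expect_equal(artifact_rate(2, 200), 1)
  expect_equal(artifact_rate(200, 200), 100)
  expect_error(artifact_rate(1, 0))

  expect_equal(scaled_absolute_error(810, 800, 1000), 1)
  expect_equal(scaled_absolute_error(5, 5, 10), 0)
  expect_equal(scaled_absolute_error(0, 7, 7), 100)
  expect_error(scaled_absolute_error(1, 2, 0))
})

test_that("Spearman ranking bands follow the thresholds", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5)
  s <- spearman_ranked(x, x)
  expect_equal(s$rho, 1)
  expect_equal(s$ranking, "high")
  expect_equal(spearman_ranked(x, -x)$rho, -1)

  # monotone but noisy ranks: moderate band when significant
  set.seed(2)
  y <- rank(x) + rnorm(8, sd = 1.2)
  s2 <- spearman_ranked(x, y)
  expect_true(s2$ranking %in% c("high", "moderate", "low", "none"))
  if (is.finite(s2$p) && s2$p < 0.05 && s2$rho > 0.9) {
    expect_equal(s2$ranking, "high")
  }

  # non-significant association is ranked none regardless of rho
  set.seed(4)
  s3 <- spearman_ranked(rnorm(6), rnorm(6))
  if (s3$p >= 0.05) expect_equal(s3$ranking, "none")

  expect_equal(spearman_ranked(rep(1, 6), 1:6)$ranking, "none")
  expect_error(spearman_ranked(1:3, 1:3), "n >= 5")
})

test_that("Bland-Altman agreement reproduces a published summary row", {
  # mean-IBI baseline row: bias 1.70, CI half-width 1.53, n = 14
  n <- 14
  sd_d <- 1.53 * sqrt(n) / qt(0.975, n - 1)
  d <- 1.70 + sd_d * as.numeric(scale(1:n))
  gs <- seq(700, 950, length.out = n)[order(sin(1:n))]  # varied means
  ba <- bland_altman(gs + d, gs)
  expect_equal(ba$bias, 1.70, tolerance = 1e-9)
  expect_equal(ba$bias_ci_halfwidth, 1.53, tolerance = 1e-9)
  expect_equal(ba$loa_upper, 6.89, tolerance = 0.05)
  expect_equal(ba$loa_lower, -3.49, tolerance = 0.05)
  expect_lt(ba$bias_p, 0.05)
})

test_that("Bland-Altman handles exact and degenerate cases", {
  gs <- c(10, 12, 15, 13, 18, 11, 16)
  same <- bland_altman(gs, gs)
  expect_equal(same$bias, 0)
  expect_equal(same$loa_upper, 0)
  expect_true(same$degenerate)
  expect_true(is.nan(same$bias_p))

  off <- bland_altman(gs + 5, gs)
  expect_equal(off$bias, 5)
  expect_equal(off$sd_diff, 0)
  expect_equal(off$loa_upper, 5)
  expect_equal(off$loa_lower, 5)
  expect_error(bland_altman(1:4, 2:5), "n >= 5")
})

test_that("LOA and bias CI derive consistently from one SD", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    e4 <- rnorm(n, 100, 10)
    gs <- rnorm(n, 100, 10)
    ba <- bland_altman(e4, gs)
    lhs <- (ba$loa_upper - ba$bias) / 1.96 * qt(0.975, n - 1) / sqrt(n)
    expect_equal(lhs, ba$bias_ci_halfwidth, tolerance = 1e-12)
    expect_gte(ba$loa_upper, ba$bias)
    expect_lte(ba$loa_lower, ba$bias)
  }
})

test_that("a trend in the differences switches on transformed limits", {
  set.seed(9)
  gs <- seq(50, 150, length.out = 20)
  e4 <- gs * 1.3 + rnorm(20, sd = 1)  # spread grows with the mean
  ba <- bland_altman(e4, gs)
  expect_true(ba$loa_transformed)
  expect_lt(ba$trend$p, 0.05)
  expect_gt(ba$trend$slope, 0)
})

test_that("Friedman test matches the reference implementation and handles ties", {
  set.seed(11)
  m <- matrix(rnorm(14 * 6), 14, 6)
  fr <- friedman_with_posthoc(m)
  ref <- stats::friedman.test(m)
  expect_equal(fr$chi_squared, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(fr$p, ref$p.value, tolerance = 1e-9)
  expect_equal(fr$df, 5)

  tied <- matrix(rep(1:4, 3), 4, 3)
  fr0 <- friedman_with_posthoc(tied)
  expect_equal(fr0$chi_squared, 0)
  expect_equal(fr0$decision, "maintain H0")

  expect_error(friedman_with_posthoc(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("a uniformly largest condition dominates the post hoc comparisons", {
  set.seed(12)
  m <- matrix(rnorm(14 * 3), 14, 3)
  m[, 3] <- m[, 3] + 10  # condition 3 largest in every subject
  colnames(m) <- c("A", "B", "C")
  fr <- friedman_with_posthoc(m)
  expect_equal(fr$decision, "reject H0")
  ph <- fr$posthoc
  with_c <- ph$condition_a == "C" | ph$condition_b == "C"
  expect_lt(max(ph$p_adjusted[with_c]), min(ph$p_adjusted[!with_c]))
})

test_that("exact Friedman p matches exhaustive enumeration", {
  set.seed(13)
  m <- matrix(rnorm(4 * 3), 4, 3)
  fr <- friedman_with_posthoc(m, exact = TRUE)

  # independent brute-force enumeration over within-row permutations
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  stat <- function(mm) {
    R <- t(apply(mm, 1, rank))
    12 * sum((colSums(R) - 4 * 2)^2) / (4 * 3 * 4)
  }
  obs <- stat(m)
  count <- 0
  for (i1 in 1:6) for (i2 in 1:6) for (i3 in 1:6) for (i4 in 1:6) {
    mm <- rbind(m[1, perms[i1, ]], m[2, perms[i2, ]],
                m[3, perms[i3, ]], m[4, perms[i4, ]])
    if (stat(mm) >= obs - 1e-12) count <- count + 1
  }
  expect_equal(fr$p, count / 6^4, tolerance = 1e-12)
  expect_equal(fr$chi_squared, obs, tolerance = 1e-9)
})

test_that("normality gate wraps Shapiro-Wilk with the 5% rule", {
  two_valued <- rep(c(1, 2), 7)
  g <- normality_gate(two_valued)
  expect_lt(g$p, 0.05)
  expect_false(g$normal)
  expect_error(normality_gate(c(1, 2)), "3 <= n")
  expect_error(normality_gate(rnorm(60)), "3 <= n")

  # type-I calibration: clean normal samples pass at least 90% of the time
  ok <- 0
  for (s in 1:100) {
    set.seed(s)
    if (normality_gate(rnorm(14))$normal) ok <- ok + 1
  }
  expect_gte(ok, 90)
})
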