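# Regression, Bland-Altman, rank tests, normality gate, summary tables.

test_that("least squares recovers exact lines and matches normal equations", {
  x <- c(1, 2, 3, 4, 5)
  fit <- least_squares_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  # constant y: slope 0, R^2 defined as 0
  fit0 <- least_squares_fit(x, rep(3, 5))
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r_squared, 0)
  expect_suvpair_error(least_squares_fit(rep(1, 5), x),
                       "suvpair_degenerate_input")
  # random sample vs closed-form normal equations
  set.seed(81)
  for (i in 1:5) {
    xs <- rnorm(20); ys <- 1.5 * xs + rnorm(20)
    fit <- least_squares_fit(xs, ys)
    sxx <- sum((xs - mean(xs))^2)
    slope <- sum((xs - mean(xs)) * (ys - mean(ys))) / sxx
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, mean(ys) - slope * mean(xs), tolerance = 1e-10)
  }
})

test_that("Bland-Altman uses median and interpolated 2.5/97.5 percentiles", {
  s <- c(3, 5, 8, 13, 21)
  b0 <- bland_altman_median(s, s)
  expect_equal(b0$median_diff, 0)
  expect_equal(c(b0$loa_low, b0$loa_high), c(0, 0))
  b1 <- bland_altman_median(s, 1.2 * s)
  expect_equal(b1$median_diff, 20)
  expect_equal(c(b1$loa_low, b1$loa_high), c(20, 20))
  # order-statistic interpolation at h = (n-1)p + 1 on known differences
  b2 <- bland_altman_median(rep(100, 5), c(101, 102, 103, 104, 105))
  expect_equal(b2$median_diff, 3)
  expect_equal(b2$loa_low, 1.1)
  expect_equal(b2$loa_high, 4.9)
  expect_equal(b2$pair_means, (rep(100, 5) + c(101:105)) / 2)
  expect_suvpair_error(bland_altman_median(c(0, 1, 2), c(1, 2, 3)),
                       "suvpair_invalid_argument")
})

test_that("Bland-Altman LOA contain ~95% of a large sample", {
  set.seed(91)
  s <- exp(rnorm(1000, 2, 0.3))
  p <- s * exp(rnorm(1000, 0.2, 0.25))
  ba <- bland_altman_median(s, p)
  frac <- mean(ba$differences >= ba$loa_low & ba$differences <= ba$loa_high)
  expect_gte(frac, 0.94)
  expect_lte(frac, 0.96)
  expect_true(ba$loa_low <= ba$median_diff && ba$median_diff <= ba$loa_high)
})

test_that("Wilcoxon signed-rank: exact branch equals full enumeration", {
  # all-positive, no ties: p = 2 / 2^6
  res <- wilcoxon_signed_rank(c(1.2, 2.5, 3.1, 4.7, 5.3, 6.9))
  expect_equal(res$method, "exact")
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 2 / 64)
  # antisymmetric pair -> p = 1 (tie in |d| forces the approximate branch)
  expect_equal(wilcoxon_signed_rank(c(2.5, -2.5))$p_value, 1)
  # enumeration oracle over random no-tie samples, n <= 10
  set.seed(101)
  for (i in 1:8) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (anyDuplicated(abs(d)) || length(d) < 2) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_signed_rank_p(d),
                 tolerance = 1e-12)
  }
  expect_suvpair_error(wilcoxon_signed_rank(c(0, 0, 0)),
                       "suvpair_degenerate_input")
})

test_that("Wilcoxon approximate branch tracks the exact branch at crossover", {
  set.seed(111)
  for (i in 1:6) {
    d <- rnorm(25, 0.3, 1)  # the exact branch's upper limit
    exact <- wilcoxon_signed_rank(d, exact_max = 25)
    approx <- wilcoxon_signed_rank(d, exact_max = 5)
    expect_equal(exact$method, "exact")
    expect_equal(approx$method, "normal_approx")
    expect_lt(abs(exact$p_value - approx$p_value), 0.01)
  }
})

test_that("Mann-Whitney U: exact branch equals full enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)  # 2 / C(6,3)
  expect_equal(res$method, "exact")
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(121)
  for (i in 1:8) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    a <- round(rnorm(m), 3); b <- round(rnorm(n, 0.5), 3)
    if (anyDuplicated(c(a, b))) next
    expect_equal(mann_whitney_u(a, b)$p_value,
                 oracle_mann_whitney_p(a, b), tolerance = 1e-12)
    expect_equal(mann_whitney_u(a, b, "greater")$p_value,
                 oracle_mann_whitney_p(a, b, "greater"), tolerance = 1e-12)
  }
  expect_suvpair_error(mann_whitney_u(numeric(0), 1:3),
                       "suvpair_invalid_argument")
})

test_that("Mann-Whitney one-sided p falls as one group shifts upward", {
  a <- c(1.1, 2.3, 3.2, 4.9, 5.5)
  b <- c(0.8, 1.9, 3.0, 4.1, 5.2)
  ps <- sapply(c(0, 0.5, 1, 2), function(shift) {
    mann_whitney_u(a + shift, b, "greater")$p_value
  })
  expect_true(all(diff(ps) <= 0))
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(131)
  a <- rnorm(12, 1); b <- rnorm(10)
  expect_equal(mann_whitney_u(exp(a), exp(b))$p_value,
               mann_whitney_u(a, b)$p_value)
  # signed-rank invariance needs a rank-preserving map of |d|; scaling works
  d <- rnorm(14, 0.3)
  expect_equal(wilcoxon_signed_rank(d * 7)$p_value,
               wilcoxon_signed_rank(d)$p_value)
})

test_that("normality gate reproduces a published Shapiro-Wilk example", {
  # weights of 11 men from the original Shapiro-Wilk paper; published W = 0.79
  w <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195, 236)
  res <- normality_gate(w)
  expect_equal(round(res$W, 2), 0.79)
  expect_false(res$is_normal)
  # heavy-tailed fixture: one extreme outlier among 20 normals
  set.seed(141)
  x <- c(rnorm(20), 25)
  expect_false(normality_gate(x)$is_normal)
  expect_suvpair_error(normality_gate(rep(1, 10)), "suvpair_degenerate_input")
  expect_suvpair_error(normality_gate(c(1, 2)), "suvpair_invalid_argument")
})

test_that("size-stratified summary matches hand computation", {
  paired <- data.frame(
    volume_cm3 = 1:8,
    spect_suv_max = rep(100, 8),
    pet_suv_max = 100 + c(10, 20, 30, 40, 50, 60, 70, 80)
  )
  tab <- size_stratified_summary(paired, measures = "suv_max", n_strata = 2)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n, c(4L, 4L))
  expect_equal(tab$median_diff_pct, c(median(c(10, 20, 30, 40)),
                                      median(c(50, 60, 70, 80))))
  expect_equal(tab$iqr_low_pct[1], unname(quantile(c(10, 20, 30, 40), 0.25)))
  # differences independent of volume -> equal stratum medians
  paired2 <- data.frame(volume_cm3 = runif(40, 1, 60),
                        spect_suv_max = rep(10, 40),
                        pet_suv_max = rep(12, 40))
  tab2 <- size_stratified_summary(paired2, measures = "suv_max")
  expect_true(all(tab2$median_diff_pct == 20))
  # uneven split puts the extra record in the earliest stratum
  paired3 <- paired[1:7, ]
  tab3 <- size_stratified_summary(paired3, measures = "suv_max", n_strata = 2)
  expect_equal(tab3$n, c(4L, 3L))
  expect_suvpair_error(
    size_stratified_summary(paired[1:2, ], measures = "suv_max", n_strata = 4),
    "suvpair_invalid_argument")
})

test_that("site background summary matches hand computation", {
  paired <- data.frame(
    site = rep("spine", 6),
    spect_suv_mean_bg = c(5.0, 5.5, 6.0, 6.5, 7.0, 7.5),
    pet_suv_mean_bg = c(6.1, 6.4, 7.3, 7.6, 8.4, 9.2)
  )
  tab <- site_background_summary(paired)
  expect_equal(tab$spect_median, median(paired$spect_suv_mean_bg))
  expect_equal(tab$pet_median, median(paired$pet_suv_mean_bg))
  d <- paired$pet_suv_mean_bg - paired$spect_suv_mean_bg
  expect_equal(tab$diff_median, median(d))
  expect_equal(tab$diff_iqr_low, unname(quantile(d, 0.25)))
  expect_equal(tab$wilcoxon_p, wilcoxon_signed_rank(d)$p_value)
  # constant backgrounds: IQR width 0
  pc <- data.frame(site = rep("skull", 5),
                   spect_suv_mean_bg = rep(2, 5),
                   pet_suv_mean_bg = rep(2.6, 5))
  tc <- site_background_summary(pc)
  expect_equal(tc$spect_iqr_low, tc$spect_iqr_high)
  expect_suvpair_error(site_background_summary(paired, sites = "femur"),
                       "suvpair_invalid_argument")
})
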