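# Regional statistics and agreement analytics (rank-test enumeration
# oracles live in the helper).

test_that("regional means use valid voxels only, with sample SD", {
  arr <- array(0L, dim = c(3, 3, 1))
  arr[1:3] <- 1L; arr[4:6] <- 2L; arr[7:9] <- 3L
  lv <- lv_from_array(arr)
  val <- array(NA_real_, dim = dim(arr))
  val[1:3] <- 1200                       # uniform region
  val[4:6] <- c(10, 20, 30)              # hand-computed mean/sd
  val[7:9] <- c(100, 999, 300)           # middle voxel invalidated
  valid <- !is.na(val); valid[8] <- FALSE
  pm <- relaxomap:::parameter_map(val, val, NULL, val * 0, valid,
                                  "MULTIECHO_T2", list())
  rs <- region_means(pm, lv)
  expect_equal(rs$mean_ms, c(1200, 20, 200))
  expect_equal(rs$sd_ms, c(0, 10, sd(c(100, 300))))
  expect_equal(rs$n_valid_voxels, c(3L, 3L, 2L))
  expect_false(any(rs$absent))
  # a region with no valid voxel is flagged absent, not dropped
  valid[7:9] <- FALSE
  pm2 <- relaxomap:::parameter_map(val, val, NULL, val * 0, valid,
                                   "MULTIECHO_T2", list())
  rs2 <- region_means(pm2, lv)
  expect_true(rs2$absent[3])
  expect_equal(nrow(rs2), 3L)
})

test_that("Bland-Altman limits are mean +/- 2 sample SD of the differences", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ba0$mean_diff, ba0$sd_diff, ba0$lower_limit, ba0$upper_limit),
               c(0, 0, 0, 0))
  ba <- bland_altman(c(100, 200), c(110, 190))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(200), tolerance = 1e-12)
  expect_equal(ba$lower_limit, -2 * sqrt(200))
  expect_equal(ba$upper_limit, 2 * sqrt(200))
  # shifting y by c shifts the mean difference by -c, sd unchanged
  x <- c(5, 9, 14, 20); y <- c(6, 8, 15, 19)
  b1 <- bland_altman(x, y); b2 <- bland_altman(x, y + 3)
  expect_equal(b2$mean_diff, b1$mean_diff - 3)
  expect_equal(b2$sd_diff, b1$sd_diff)
  expect_error(bland_altman(1:3, 1:4), "mismatch")
})

test_that("regression to identity recovers exact lines and percent errors", {
  r <- regression_to_identity(c(0, 1, 2), c(1, 3, 5))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  x <- c(10, 20, 30, 40)
  ri <- regression_to_identity(x, x)
  expect_equal(c(ri$slope, ri$intercept, ri$r_squared, ri$mean_percent_error),
               c(1, 0, 1, 0))
  expect_error(regression_to_identity(rep(5, 4), 1:4), "constant")
  # symmetric percent error, single pair: 2/101*100
  expect_equal(mean_percent_error(100, 102), 2 / 101 * 100)
})

test_that("Mann-Whitney exact branch enumerates correctly", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_two_sided, 1 / 3)
  expect_true(r$exact)
  # identical multisets: p capped at 1; symmetry in the arguments
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1)
  a <- c(1.2, 3.4, 2.2); b <- c(0.5, 2.9, 2.2, 4.0)
  expect_equal(mann_whitney_u(a, b)$p_two_sided,
               mann_whitney_u(b, a)$p_two_sided)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact rank tests match brute-force enumeration for n <= 8", {
  set.seed(17)
  for (n1 in 2:4) for (n2 in 2:4) {
    x <- sample(1:6, n1, replace = TRUE)  # replace=TRUE provokes ties
    y <- sample(1:6, n2, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_two_sided, mw_oracle_p(x, y),
                 info = sprintf("MW n1=%d n2=%d", n1, n2))
  }
  for (n in 3:8) {
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(d)$p_two_sided, wsr_oracle_p(d),
                 info = sprintf("WSR n=%d", n))
  }
  # tie-free cases also agree with the established implementation
  x <- c(1.1, 4.2, 2.7); y <- c(3.3, 5.1, 0.4, 6.2)
  expect_equal(mann_whitney_u(x, y)$p_two_sided,
               wilcox.test(x, y, exact = TRUE)$p.value)
  d <- c(1.5, -2.2, 3.1, -0.4, 2.8)
  expect_equal(wilcoxon_signed_rank(d)$p_two_sided,
               wilcox.test(d, exact = TRUE)$p.value)
})

test_that("Wilcoxon signed-rank handles signs, zeros and degenerate input", {
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$w_minus, 0)
  expect_equal(r$p_two_sided, 0.25)
  expect_equal(wilcoxon_signed_rank(c(-1, -2, -3))$p_two_sided, 0.25)
  expect_equal(wilcoxon_signed_rank(c(5))$p_two_sided, 1)
  expect_equal(wilcoxon_signed_rank(c(0, 0, 2))$n_nonzero, 1L)  # zeros dropped
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
})

test_that("the Shapiro-Wilk gate rejects two-point data and is calibrated under the null", {
  set.seed(23)
  expect_lt(shapiro_wilk(sample(c(0, 1), 200, replace = TRUE)), 0.05)
  ps <- replicate(200, shapiro_wilk(rnorm(100)))
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.1)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("scan-rescan reporting flags large differences and nothing else", {
  ph <- small_phantom()
  mk_stats <- function(seed) {
    s <- simulate_multiecho_series(ph$maps$t2_ms, ph$maps$proton_density,
                                   noise_sigma = 20, seed = seed)
    region_means(fit_t2_map(s, fit_options(min_signal = 0)), ph$lv)
  }
  s1 <- mk_stats(101)
  # identical scans: all flags true, "no difference" notice
  rep0 <- scan_rescan_report(s1, s1)
  expect_true(all(rep0$table$within_2sd))
  expect_true(is.na(rep0$wilcoxon_p))
  expect_equal(rep0$note, "no difference")
  # an injected 3-SD shift in one region flips exactly that flag
  s_shift <- s1
  s_shift$mean_ms[4] <- s1$mean_ms[4] + 3 * s1$sd_ms[4]
  expect_false(scan_rescan_report(s1, s_shift)$table$within_2sd[4])
  # replicate scans (new noise seed only): >= 90% of regions within 2 SD
  flags <- sapply(102:111, function(sd)
    mean(scan_rescan_report(s1, mk_stats(sd))$table$within_2sd))
  expect_gte(mean(flags), 0.9)
  # regression of rescan means sits near identity
  rep1 <- scan_rescan_report(s1, mk_stats(115))
  expect_equal(rep1$regression$slope, 1, tolerance = 0.1)
  expect_gt(rep1$regression$r_squared, 0.98)
})
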