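# Regional statistics and agreement analytics: regional means, Bland-Altman
# limits, regression to identity, symmetric mean percent error, exact
# nonparametric tests and scan-rescan reports.
#
# Conventions: all standard deviations are sample SDs (n - 1 denominator);
# Bland-Altman limits are mean +/- 2 SD exactly (not 1.96 SD); the percent
# error between paired measurements is the symmetric form
# |x - y| / ((x + y) / 2) * 100, so reports are direction-free.

#' Per-region statistics of a fitted parameter map
#'
#' Mean and sample SD of the fitted relaxation time over the valid voxels
#' of each lut region.  Regions with no valid voxel are kept in the table
#' and flagged `absent` rather than dropped.
#'
#' @param pm A `parameter_map` (see [fit_t1_map()]).
#' @param lv A [label_volume()] on the same grid.
#' @return A `data.frame`: `label_id`, `region_name`, `n_valid_voxels`,
#'   `mean_ms`, `sd_ms`, `absent`.
#' @export
region_means <- function(pm, lv) {
  stopifnot(inherits(pm, "parameter_map"), inherits(lv, "label_volume"))
  if (!identical(dim(pm$value_ms), dim(lv$labels)))
    stop_relaxo("grid mismatch: map %s vs labels %s",
                paste(dim(pm$value_ms), collapse = "x"),
                paste(dim(lv$labels), collapse = "x"))
  ids <- lv$lut$label_id
  out <- data.frame(label_id = ids, region_name = lv$lut$region_name,
                    n_valid_voxels = 0L, mean_ms = NA_real_, sd_ms = NA_real_,
                    absent = TRUE, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    v <- pm$value_ms[lv$labels == ids[i] & pm$valid]
    n <- length(v)
    out$n_valid_voxels[i] <- n
    if (n > 0L) {
      out$mean_ms[i] <- mean(v)
      out$sd_ms[i] <- if (n > 1L) stats::sd(v) else 0
      out$absent[i] <- FALSE
    }
  }
  out
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = x - y`; limits of agreement are `mean(d) +/- 2 sd(d)`
#' with the sample SD.
#'
#' @param x,y Paired measurements, equal length >= 2.
#' @return A list: `mean_diff`, `sd_diff`, `lower_limit`, `upper_limit`,
#'   `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    stop_relaxo("length mismatch: %d vs %d", length(x), length(y))
  if (length(x) < 2L) stop_relaxo("need >= 2 pairs")
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       lower_limit = m - 2 * s, upper_limit = m + 2 * s, n = length(d))
}

#' Regression to identity and symmetric mean percent error
#'
#' Ordinary least squares of `y` on `x` together with the symmetric mean
#' percent error `mean(|x - y| / ((x + y) / 2)) * 100`.  Perfect agreement
#' gives slope 1, intercept 0, R-squared 1 and 0% error.
#'
#' @param x,y Paired measurements; `n >= 3` and `x` non-constant for the
#'   regression (the percent error alone tolerates any `n >= 1`).
#' @return A list: `slope`, `intercept`, `r_squared`, `mean_percent_error`,
#'   `n`.
#' @export
regression_to_identity <- function(x, y) {
  if (length(x) != length(y))
    stop_relaxo("length mismatch: %d vs %d", length(x), length(y))
  if (length(x) < 3L) stop_relaxo("need >= 3 pairs for regression")
  if (stats::sd(x) == 0) stop_relaxo("x is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       mean_percent_error = mean_percent_error(x, y),
       n = length(x))
}

#' Symmetric mean percent error between paired measurements
#' @param x,y Paired positive measurements.
#' @return `mean(|x - y| / ((x + y) / 2)) * 100`.
#' @export
mean_percent_error <- function(x, y) {
  if (length(x) != length(y))
    stop_relaxo("length mismatch: %d vs %d", length(x), length(y))
  mean(abs(x - y) / ((x + y) / 2)) * 100
}

#' Mann-Whitney U test (two independent samples)
#'
#' Exact p by complete enumeration of all `choose(n1 + n2, n1)` group
#' assignments when the combined sample size is at most `exact_limit`
#' (mid-ranks, so ties are handled exactly); otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_limit Combined-size threshold for the exact branch
#'   (default 12).
#' @return A list: `u_statistic` (U of `x`), `p_two_sided`, `exact`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  if (length(x) == 0L || length(y) == 0L) stop_relaxo("samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  comb <- c(x, y)
  rk <- rank(comb)  # mid-ranks
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_limit) {
    sets <- utils::combn(n1 + n2, n1)
    us <- apply(sets, 2, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(us <= u + eps), mean(us >= u - eps)))
    list(u_statistic = u, p_two_sided = p, exact = TRUE)
  } else {
    n <- n1 + n2
    ties <- table(comb)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(u_statistic = u, p_two_sided = p, exact = FALSE)
  }
}

#' Wilcoxon signed-rank test (paired differences)
#'
#' Zero differences are dropped (Wilcoxon's original treatment); ties in
#' `|d|` get mid-ranks.  Exact p by enumeration of all `2^n` sign patterns
#' when `n <= exact_limit`, else normal approximation with tie correction.
#'
#' @param d Paired differences with at least one nonzero value.
#' @param exact_limit Size threshold for the exact branch (default 12).
#' @return A list: `w_plus`, `w_minus`, `statistic` (min of the two),
#'   `p_two_sided`, `n_nonzero`, `exact`.
#' @export
wilcoxon_signed_rank <- function(d, exact_limit = 12L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop_relaxo("all differences are zero; test undefined")
  rk <- rank(abs(d))
  wp <- sum(rk[d > 0])
  wm <- sum(rk[d < 0])
  if (n <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% rk)  # W+ under each sign pattern
    eps <- 1e-9
    p <- min(1, 2 * min(mean(ws <= wp + eps), mean(ws >= wp - eps)))
    list(w_plus = wp, w_minus = wm, statistic = min(wp, wm),
         p_two_sided = p, n_nonzero = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (wp - mu - sign(wp - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(w_plus = wp, w_minus = wm, statistic = min(wp, wm),
         p_two_sided = p, n_nonzero = n, exact = FALSE)
  }
}

#' Shapiro-Wilk normality p-value
#'
#' Thin wrapper around [stats::shapiro.test()], used as the gate for
#' switching to nonparametric tests.  Constant samples are an error (the
#' statistic is undefined there).
#'
#' @param x Sample with 3 <= n <= 5000.
#' @return The p-value.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3L || length(x) > 5000L)
    stop_relaxo("Shapiro-Wilk requires 3 <= n <= 5000, got %d", length(x))
  stats::shapiro.test(x)$p.value
}

#' Agreement report between two sets of paired regional values
#'
#' Combines everything used to compare two pipelines/centers/scans on the
#' same regions: Bland-Altman statistics, regression to identity, symmetric
#' mean percent error, Mann-Whitney (unpaired) and Wilcoxon signed-rank
#' (paired) tests, and Shapiro-Wilk normality p-values for both samples.
#' If either sample fails the normality gate at `alpha`, the nonparametric
#' p-values are the primary result (`primary_test`).
#'
#' @param x,y Paired per-region values (same regions, same order).
#' @param alpha Significance level for the normality gate and reported
#'   significance calls (default 0.01).
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(x, y, alpha = 0.01) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_relaxo("need >= 3 complete pairs, got %d", length(x))
  ba <- bland_altman(x, y)
  reg <- regression_to_identity(x, y)
  mw <- mann_whitney_u(x, y)
  d <- x - y
  wx <- if (any(d != 0)) wilcoxon_signed_rank(d) else
    list(w_plus = 0, w_minus = 0, statistic = 0, p_two_sided = NA_real_,
         n_nonzero = 0L, exact = TRUE)
  sw_x <- if (stats::sd(x) > 0) shapiro_wilk(x) else NA_real_
  sw_y <- if (stats::sd(y) > 0) shapiro_wilk(y) else NA_real_
  nonnormal <- (!is.na(sw_x) && sw_x < alpha) || (!is.na(sw_y) && sw_y < alpha)
  structure(list(n_pairs = length(x), bland_altman = ba, regression = reg,
                 mean_percent_error = reg$mean_percent_error,
                 mann_whitney_p = mw$p_two_sided,
                 wilcoxon_p = wx$p_two_sided,
                 shapiro_p_x = sw_x, shapiro_p_y = sw_y,
                 alpha = alpha,
                 primary_test = if (nonnormal) "nonparametric" else "parametric"),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<agreement_report> n = %d pairs (alpha = %g, %s primary)\n",
    "  Bland-Altman: mean diff %.4g, limits [%.4g, %.4g]\n",
    "  regression:   y = %.4gx + %.4g (R2 = %.4g)\n",
    "  mean %% error: %.3g%%   Mann-Whitney p = %.3g   Wilcoxon p = %.3g\n"),
    x$n_pairs, x$alpha, x$primary_test,
    x$bland_altman$mean_diff, x$bland_altman$lower_limit,
    x$bland_altman$upper_limit,
    x$regression$slope, x$regression$intercept, x$regression$r_squared,
    x$mean_percent_error, x$mann_whitney_p, x$wilcoxon_p))
  invisible(x)
}

#' Scan-rescan report
#'
#' Compares per-region statistics from two acquisitions of the same
#' subject.  A region is within tolerance when the absolute difference of
#' its two means is below two standard deviations, using the larger of the
#' two regional SDs as the yardstick.  Paired regional means also get a
#' Wilcoxon signed-rank test and a regression to identity.
#'
#' @param s1,s2 [region_means()] tables over the same lut.
#' @return A list: `table` (per-region `diff_ms`, `within_2sd`),
#'   `wilcoxon_p` (`NA` with `note = "no difference"` when all diffs are
#'   zero), `regression`, `n_regions`.
#' @export
scan_rescan_report <- function(s1, s2) {
  if (!identical(s1$label_id, s2$label_id) ||
      !identical(s1$region_name, s2$region_name))
    stop_relaxo("region tables do not share a lut")
  keep <- !s1$absent & !s2$absent
  diff <- s1$mean_ms - s2$mean_ms
  yard <- 2 * pmax(s1$sd_ms, s2$sd_ms)
  tab <- data.frame(label_id = s1$label_id, region_name = s1$region_name,
                    mean1_ms = s1$mean_ms, mean2_ms = s2$mean_ms,
                    diff_ms = diff, within_2sd = abs(diff) <= yard,
                    stringsAsFactors = FALSE)
  d <- diff[keep]
  if (all(d == 0)) {
    wp <- NA_real_; note <- "no difference"
  } else {
    wp <- wilcoxon_signed_rank(d)$p_two_sided; note <- NULL
  }
  reg <- regression_to_identity(s1$mean_ms[keep], s2$mean_ms[keep])
  list(table = tab, wilcoxon_p = wp, note = note, regression = reg,
       n_regions = sum(keep))
}
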