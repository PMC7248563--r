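# Voxel-per-voxel nonlinear estimation of T1 and T2 maps.
#
# Every voxel is fitted independently (no spatial coupling).  Two optimizer
# backends are available: Levenberg-Marquardt (minpack.lm) and Nelder-Mead
# simplex (stats::optim), both minimizing the same sum-of-squares, so their
# fitted maps should agree to well under a percent on clean data.

#' Fitting options
#'
#' @param optimizer `"LEAST_SQUARES_LM"` (Levenberg-Marquardt) or
#'   `"SIMPLEX"` (Nelder-Mead).
#' @param max_iterations Iteration cap per voxel (default 500).
#' @param convergence_tol Relative parameter-change tolerance (default 1e-6).
#' @param multistart_null_points Number of candidate null-point TIs used to
#'   initialize T1 (the observed signal minimum plus its neighbours);
#'   guards the magnitude-IR fit against the null-point local minimum.
#' @param t1_bounds_ms,t2_bounds_ms Plausibility bounds applied by
#'   [filter_map()]: fitted values must be positive and no greater than the
#'   upper bound (3000 ms for T1, 300 ms for T2 by default).
#' @param min_signal Voxels whose maximum signal is at or below this are
#'   skipped as background.  `NULL` (default) estimates it at fit time as 3x
#'   the background noise scale inferred from the grid's border voxels.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(optimizer = c("LEAST_SQUARES_LM", "SIMPLEX"),
                        max_iterations = 500L,
                        convergence_tol = 1e-6,
                        multistart_null_points = 3L,
                        t1_bounds_ms = c(0, 3000),
                        t2_bounds_ms = c(0, 300),
                        min_signal = NULL) {
  optimizer <- match.arg(optimizer)
  if (!is_count(max_iterations)) stop_relaxo("max_iterations must be a positive count")
  if (convergence_tol <= 0) stop_relaxo("convergence_tol must be > 0")
  if (!is_count(multistart_null_points))
    stop_relaxo("multistart_null_points must be a positive count")
  if (t1_bounds_ms[2] <= 0 || t2_bounds_ms[2] <= 0)
    stop_relaxo("bounds must be positive")
  if (!is.null(min_signal) && min_signal < 0) stop_relaxo("min_signal must be >= 0")
  structure(list(optimizer = optimizer,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 multistart_null_points = as.integer(multistart_null_points),
                 t1_bounds_ms = t1_bounds_ms, t2_bounds_ms = t2_bounds_ms,
                 min_signal = min_signal),
            class = "fit_options")
}

parameter_map <- function(value_ms, amplitude, secondary, residual_rms, valid,
                          modality, provenance) {
  structure(list(value_ms = value_ms, amplitude = amplitude,
                 secondary = secondary, residual_rms = residual_rms,
                 valid = valid, modality = modality, provenance = provenance),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> %s, %s grid, %d/%d valid voxels\n",
              x$modality, paste(dim(x$value_ms), collapse = "x"),
              sum(x$valid), length(x$valid)))
  invisible(x)
}

# Background scale from the grid's six border faces: the median of border
# voxels' per-voxel maximum signal, converted from the Rician floor mean
# (sigma * sqrt(pi/2)) back to sigma.  Zero when the border is silent.
estimate_min_signal <- function(data4d) {
  shp <- dim(data4d)[1:3]
  border <- array(FALSE, dim = shp)
  border[c(1, shp[1]), , ] <- TRUE
  border[, c(1, shp[2]), ] <- TRUE
  border[, , c(1, shp[3])] <- TRUE
  mx <- apply(array(data4d, dim = c(prod(shp), dim(data4d)[4]))[which(border), ,
                                                                drop = FALSE],
              1, max)
  3 * stats::median(mx) / sqrt(pi / 2)
}

# Single-voxel magnitude-IR fit with multistart over candidate null TIs.
# Returns c(a, b, t1, ssr) or NULL on failure.
fit_voxel_ir <- function(y, ti, options) {
  n <- length(ti)
  i0 <- which.min(y)
  half <- (options$multistart_null_points - 1L) %/% 2L
  offs <- seq(-half, options$multistart_null_points - 1L - half)
  cand <- unique(pmax(1L, pmin(n, i0 + offs)))
  a0 <- max(y)
  best <- NULL
  ssq <- function(p) {
    if (p[3] <= 0 || p[1] < 0) return(1e300)
    sum((y - abs(p[1] * (1 - p[2] * exp(-ti / p[3]))))^2)
  }
  for (j in cand) {
    t10 <- ti[j] / log(2)
    start <- c(a0, 2, t10)
    if (options$optimizer == "LEAST_SQUARES_LM") {
      r <- try(minpack.lm::nls.lm(
        par = start,
        lower = c(0, 0, 1e-3), upper = c(Inf, 4, 1e6),
        fn = function(p) y - abs(p[1] * (1 - p[2] * exp(-ti / p[3]))),
        control = minpack.lm::nls.lm.control(
          maxiter = min(options$max_iterations, 1024L),
          ptol = options$convergence_tol, ftol = options$convergence_tol^2)),
        silent = TRUE)
      if (inherits(r, "try-error")) next
      fit <- list(par = r$par, ssr = r$deviance)
    } else {
      r <- stats::optim(start, ssq, method = "Nelder-Mead",
                        control = list(maxit = options$max_iterations,
                                       reltol = options$convergence_tol^2))
      # one deterministic restart from the (perturbed) optimum guards
      # against premature simplex collapse
      r2 <- stats::optim(r$par * c(1.02, 0.98, 1.05), ssq, method = "Nelder-Mead",
                         control = list(maxit = options$max_iterations,
                                        reltol = options$convergence_tol^2))
      if (r2$value < r$value) r <- r2
      fit <- list(par = r$par, ssr = r$value)
    }
    if (is.null(best) || fit$ssr < best$ssr) best <- fit
  }
  if (is.null(best)) return(NULL)
  c(best$par[1], best$par[2], best$par[3], best$ssr)
}

# Single-voxel mono-exponential T2 fit, initialized by log-linear regression
# on the first half of the echoes.  Returns c(a, t2, ssr) or NULL.
fit_voxel_t2 <- function(y, te, options) {
  n <- length(te)
  h <- seq_len(max(3L, n %/% 2L))
  pos <- y[h] > 0
  if (sum(pos) >= 2L) {
    cf <- stats::coef(stats::lm.fit(cbind(1, te[h][pos]), log(y[h][pos])))
    t20 <- -1 / cf[2]
    a0 <- exp(cf[1])
    if (!is.finite(t20) || t20 <= 0 || t20 > 1e5) t20 <- te[n] / 3
    if (!is.finite(a0) || a0 <= 0) a0 <- max(y)
  } else {
    t20 <- te[n] / 3
    a0 <- max(y)
  }
  start <- c(a0, t20)
  if (options$optimizer == "LEAST_SQUARES_LM") {
    r <- try(minpack.lm::nls.lm(
      par = start, lower = c(0, 1e-3), upper = c(Inf, 1e6),
      fn = function(p) y - p[1] * exp(-te / p[2]),
      control = minpack.lm::nls.lm.control(
        maxiter = min(options$max_iterations, 1024L),
        ptol = options$convergence_tol, ftol = options$convergence_tol^2)),
      silent = TRUE)
    if (inherits(r, "try-error")) return(NULL)
    c(r$par[1], r$par[2], r$deviance)
  } else {
    ssq <- function(p) {
      if (p[2] <= 0 || p[1] < 0) return(1e300)
      sum((y - p[1] * exp(-te / p[2]))^2)
    }
    r <- stats::optim(start, ssq, method = "Nelder-Mead",
                      control = list(maxit = options$max_iterations,
                                     reltol = options$convergence_tol^2))
    r2 <- stats::optim(r$par * c(1.02, 1.05), ssq, method = "Nelder-Mead",
                       control = list(maxit = options$max_iterations,
                                      reltol = options$convergence_tol^2))
    if (r2$value < r$value) r <- r2
    c(r$par[1], r$par[2], r$value)
  }
}

fit_map_engine <- function(series, options, modality) {
  stopifnot(inherits(series, "image_series"), inherits(options, "fit_options"))
  if (series$protocol$modality != modality)
    stop_relaxo("series modality is %s; %s required",
                series$protocol$modality, modality)
  t <- series$protocol$times_ms
  if (length(t) < 3L) stop_relaxo("need >= 3 time points, got %d", length(t))
  shp <- dim(series$data)[1:3]
  nvox <- prod(shp)
  ymat <- matrix(series$data, nrow = nvox)
  min_signal <- options$min_signal
  if (is.null(min_signal)) min_signal <- estimate_min_signal(series$data)
  mx <- ymat[, 1]
  for (k in 2:ncol(ymat)) mx <- pmax(mx, ymat[, k])
  todo <- which(mx > min_signal & mx > 0)

  value <- amp <- sec <- res <- rep(NA_real_, nvox)
  for (v in todo) {
    y <- ymat[v, ]
    if (modality == "IR_T1") {
      f <- fit_voxel_ir(y, t, options)
      if (is.null(f)) next
      amp[v] <- f[1]; sec[v] <- f[2]; value[v] <- f[3]
      res[v] <- sqrt(f[4] / length(t))
    } else {
      f <- fit_voxel_t2(y, t, options)
      if (is.null(f)) next
      amp[v] <- f[1]; value[v] <- f[2]
      res[v] <- sqrt(f[3] / length(t))
    }
  }
  pm <- parameter_map(
    value_ms = array(value, dim = shp),
    amplitude = array(amp, dim = shp),
    secondary = if (modality == "IR_T1") array(sec, dim = shp) else NULL,
    residual_rms = array(res, dim = shp),
    valid = array(!is.na(value), dim = shp),
    modality = modality,
    provenance = list(optimizer = options$optimizer, options = options,
                      n_times = length(t)))
  filter_map(pm)
}

#' Fit a T1 map voxel-per-voxel from an inversion-recovery series
#'
#' Each voxel is fitted independently with the magnitude-IR model
#' [ir_model()].  T1 is initialized from candidate signal-null inversion
#' times (`T1_0 = TI / log(2)` at the observed minimum and its neighbours)
#' and the lowest-residual start wins; [filter_map()] is then applied so
#' out-of-range fits are marked invalid.  Deterministic for fixed input and
#' options.
#'
#' @param series An [image_series()] with modality `"IR_T1"`.
#' @param options A [fit_options()].
#' @return A `parameter_map` with fields `value_ms` (T1), `amplitude` (A),
#'   `secondary` (B), `residual_rms`, `valid`.
#' @export
fit_t1_map <- function(series, options = fit_options()) {
  fit_map_engine(series, options, "IR_T1")
}

#' Fit a T2 map voxel-per-voxel from a multi-echo series
#'
#' Two-parameter mono-exponential fit per voxel, initialized by log-linear
#' regression on the first half of the echoes; [filter_map()] is applied.
#'
#' @param series An [image_series()] with modality `"MULTIECHO_T2"`.
#' @param options A [fit_options()].
#' @return A `parameter_map` (no `secondary` component).
#' @export
fit_t2_map <- function(series, options = fit_options()) {
  fit_map_engine(series, options, "MULTIECHO_T2")
}

#' Discard implausible fitted values
#'
#' Marks invalid every voxel whose fitted relaxation time is non-positive or
#' greater than the plausibility bound (3000 ms for T1, 300 ms for T2; the
#' bound itself is kept, i.e. the cut is strict on "greater than").  Values
#' are left untouched so the filter is idempotent; downstream consumers use
#' the `valid` mask only.
#'
#' @param pm A `parameter_map`.
#' @param bounds_ms Optional length-2 override of the `(lower, upper)`
#'   bound; defaults to the bound stored in the map's provenance.
#' @return The filtered `parameter_map`.
#' @export
filter_map <- function(pm, bounds_ms = NULL) {
  stopifnot(inherits(pm, "parameter_map"))
  if (is.null(bounds_ms)) {
    opts <- pm$provenance$options
    bounds_ms <- if (pm$modality == "IR_T1") opts$t1_bounds_ms else opts$t2_bounds_ms
  }
  v <- pm$value_ms
  bad <- is.na(v) | v <= bounds_ms[1] | v > bounds_ms[2]
  pm$valid <- array(!bad, dim = dim(v))
  pm
}

#' Exhaustive grid-search fit (brute-force reference)
#'
#' For each candidate relaxation time on a dense grid the amplitude terms
#' are solved by linear least squares given the decay term, and the true
#' magnitude-model residual is evaluated; the grid minimum is returned.
#' For the magnitude-IR model the amplitude solve enumerates the n+1
#' monotone polarity patterns of the signed recovery curve.  Intended as a
#' slow, optimizer-free reference for validating the fitting backends.
#'
#' @param signal Numeric vector (one voxel) or matrix (time x voxels).
#' @param protocol The [acquisition_protocol()] of the signal.
#' @param value_grid Candidate relaxation times, ms (dense over the
#'   plausibility bounds, e.g. `seq(1, 3000, by = 1)`).
#' @param model `"ir"` or `"t2"`.
#' @return A list with `best_value` and `best_residual` (sum of squares),
#'   each of length `ncol(signal)`.
#' @export
grid_search_fit <- function(signal, protocol, value_grid,
                            model = c("ir", "t2")) {
  model <- match.arg(model)
  if (length(value_grid) == 0L) stop_relaxo("value_grid is empty")
  t <- protocol$times_ms
  y <- if (is.matrix(signal)) signal else matrix(signal, ncol = 1)
  stopifnot(nrow(y) == length(t))
  n <- nrow(y); nv <- ncol(y)
  best_val <- rep(NA_real_, nv)
  best_res <- rep(Inf, nv)
  if (model == "t2") {
    for (g in value_grid) {
      e <- exp(-t / g)
      a <- pmax(0, colSums(y * e) / sum(e * e))
      r <- colSums((y - outer(e, a))^2)
      upd <- r < best_res
      best_res[upd] <- r[upd]
      best_val[upd] <- g
    }
  } else {
    # monotone polarity patterns: sign flips happen before the (single)
    # zero crossing of the recovery curve, so -...-+...+ covers them all
    pats <- sapply(0:n, function(k) c(rep(-1, k), rep(1, n - k)))
    for (g in value_grid) {
      e <- exp(-t / g)
      X <- cbind(1, e)
      xtx <- crossprod(X)
      # at very short relaxation times the decay column underflows and the
      # model degenerates to a constant; fall back to intercept-only there
      XtXi <- try(solve(xtx), silent = TRUE)
      degenerate <- inherits(XtXi, "try-error")
      for (p in seq_len(ncol(pats))) {
        z <- y * pats[, p]
        if (degenerate) {
          fitted <- matrix(abs(colMeans(z)), n, nv, byrow = TRUE)
        } else {
          cf <- XtXi %*% crossprod(X, z)        # 2 x nv
          fitted <- abs(X %*% cf)               # magnitude model residual
        }
        r <- colSums((y - fitted)^2)
        upd <- r < best_res
        best_res[upd] <- r[upd]
        best_val[upd] <- g
      }
    }
  }
  list(best_value = best_val, best_residual = best_res)
}
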