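# Round-trip and invariance properties of the voxelwise fitting backends.

noiseless_pair <- function() {
  t1 <- block_map(c(800, 1200, 1600, 2000), shape = c(4, 4, 2))
  t2 <- block_map(c(40, 60, 80, 110), shape = c(4, 4, 2))
  pd <- block_map(rep(1000, 4), shape = c(4, 4, 2))
  list(t1 = t1, t2 = t2, pd = pd,
       ir = simulate_ir_series(t1, pd, noise_sigma = 0),
       me = simulate_multiecho_series(t2, pd, noise_sigma = 0))
}

test_that("noiseless round-trips recover T1 and T2 to <0.1% with both backends", {
  px <- noiseless_pair()
  for (backend in c("LEAST_SQUARES_LM", "SIMPLEX")) {
    o <- fit_options(backend, min_signal = 0)
    f1 <- fit_t1_map(px$ir, o)
    f2 <- fit_t2_map(px$me, o)
    expect_true(all(f1$valid) && all(f2$valid))
    expect_lt(max(abs(f1$value_ms - px$t1) / px$t1), 1e-3)
    expect_lt(max(abs(f2$value_ms - px$t2) / px$t2), 1e-3)
    # amplitude and inversion factor recovered too
    expect_lt(max(abs(f1$amplitude - 1000) / 1000), 1e-3)
    expect_lt(max(abs(f1$secondary - 2)), 1e-3)
  }
})

test_that("the two backends agree voxelwise on noiseless data", {
  px <- noiseless_pair()
  lm_ <- fit_t1_map(px$ir, fit_options("LEAST_SQUARES_LM", min_signal = 0))
  nm_ <- fit_t1_map(px$ir, fit_options("SIMPLEX", min_signal = 0))
  expect_lt(max(abs(lm_$value_ms - nm_$value_ms) / lm_$value_ms), 5e-3)
})

test_that("all-zero and constant voxels end up invalid", {
  t2 <- block_map(c(0, 60, 80, 110), shape = c(4, 4, 2))
  pd <- block_map(c(0, 1000, 1000, 1000), shape = c(4, 4, 2))
  s <- simulate_multiecho_series(t2, pd, noise_sigma = 0)
  f <- fit_t2_map(s, fit_options(min_signal = 0))
  expect_true(all(!f$valid[t2 == 0]))       # zero voxels skipped
  expect_true(all(is.na(f$value_ms[t2 == 0])))
  expect_true(all(f$valid[t2 > 0]))
  # non-decaying voxel pegs at the optimizer bound and is filtered out
  dat <- s$data
  dat[1, 2, 1, ] <- 500
  s2 <- image_series(dat, s$protocol)
  f2 <- fit_t2_map(s2, fit_options(min_signal = 0))
  expect_false(f2$valid[1, 2, 1])
})

test_that("the plausibility filter cuts strictly above the bound and is idempotent", {
  px <- noiseless_pair()
  f <- fit_t2_map(px$me, fit_options(min_signal = 0))
  f$value_ms <- array(c(-1, 50, 299, 301, rep(50, length(f$value_ms) - 4)),
                      dim = dim(f$value_ms))
  g <- filter_map(f, bounds_ms = c(0, 300))
  expect_equal(as.vector(g$valid)[1:4], c(FALSE, TRUE, TRUE, FALSE))
  f$value_ms <- array(c(2999, 3000, 3001, rep(100, length(f$value_ms) - 3)),
                      dim = dim(f$value_ms))
  g1 <- filter_map(f, bounds_ms = c(0, 3000))
  expect_equal(as.vector(g1$valid)[1:3], c(TRUE, TRUE, FALSE))
  g2 <- filter_map(g1, bounds_ms = c(0, 3000))
  expect_identical(g2$valid, g1$valid)
  expect_identical(g2$value_ms, g1$value_ms)  # values untouched
})

test_that("fitting has no spatial coupling and is scale invariant", {
  ph <- small_phantom()
  s <- simulate_ir_series(ph$maps$t1_ms, ph$maps$proton_density,
                          noise_sigma = 15, seed = 2)
  o <- fit_options(min_signal = 0)
  full <- fit_t1_map(s, o)
  sub <- image_series(s$data[5:10, 5:10, 3:5, , drop = FALSE], s$protocol)
  part <- fit_t1_map(sub, o)
  expect_equal(part$value_ms, full$value_ms[5:10, 5:10, 3:5], tolerance = 1e-9)

  g <- 2.5
  s_g <- image_series(s$data * g, s$protocol)
  fg <- fit_t1_map(s_g, o)
  # scale invariance holds on signal-bearing voxels (pure-noise background
  # voxels have no well-defined optimum to preserve)
  ok <- full$valid & fg$valid & ph$lv$labels > 0
  expect_lt(max(abs(fg$value_ms[ok] - full$value_ms[ok]) / full$value_ms[ok]),
            1e-5)
  expect_lt(max(abs(fg$amplitude[ok] - g * full$amplitude[ok]) /
                  (g * full$amplitude[ok])), 1e-5)
})

test_that("grid search matches known optima and bounds the optimizers", {
  ti <- default_ir_protocol()$times_ms
  y <- ir_model(ti, 1000, 2, 1200)
  # single-point grid on matching data: residual ~ 0
  g0 <- grid_search_fit(y, default_ir_protocol(), 1200, "ir")
  expect_lt(g0$best_residual, 1e-12)
  # dense grid localizes the noiseless optimum to the grid step
  g1 <- grid_search_fit(y, default_ir_protocol(), seq(1, 3000, by = 1), "ir")
  expect_lte(abs(g1$best_value - 1200), 1)
  expect_error(grid_search_fit(y, default_ir_protocol(), numeric(0), "ir"),
               "empty")

  # optimizer residual <= grid residual (+ tolerance) on noisy voxels
  set.seed(42)
  nv <- 20
  t2s <- runif(nv, 35, 200)
  te <- default_multiecho_protocol()$times_ms
  Y <- sapply(t2s, function(t2) rician_sample(t2_model(te, 1000, t2), 20))
  gr <- grid_search_fit(Y, default_multiecho_protocol(), seq(1, 300, 1), "t2")
  for (backend in c("LEAST_SQUARES_LM", "SIMPLEX")) {
    o <- fit_options(backend, min_signal = 0)
    res <- sapply(seq_len(nv), function(i)
      relaxomap:::fit_voxel_t2(Y[, i], te, o)[3])
    expect_true(all(res <= gr$best_residual * (1 + 1e-6) + 1e-9))
  }
})
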