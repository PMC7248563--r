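test_that("zero-noise simulations equal the analytic models voxelwise", {
  t1 <- block_map(c(800, 1200, 1600, 2000))
  pd <- block_map(rep(1000, 4))
  s <- simulate_ir_series(t1, pd, noise_sigma = 0)
  ti <- s$protocol$times_ms
  for (k in seq_along(ti))
    expect_equal(s$data[, , , k],
                 array(ir_model(ti[k], 1000, 2, t1), dim = dim(t1)))
  # null point: TI = T1 log 2 gives (numerically) zero signal
  proto <- acquisition_protocol("IR_T1", c(247, 693.147, 5000), 6500)
  s0 <- simulate_ir_series(block_map(rep(1000, 4)), pd, proto, noise_sigma = 0)
  expect_lt(max(s0$data[, , , 2]), 1e-3)

  t2 <- block_map(c(40, 60, 80, 110))
  sme <- simulate_multiecho_series(t2, pd, noise_sigma = 0)
  te <- sme$protocol$times_ms
  expect_length(te, 28L)
  expect_equal(diff(te), rep(8, 27))
  for (k in c(1L, 14L, 28L))
    expect_equal(sme$data[, , , k],
                 array(t2_model(te[k], 1000, t2), dim = dim(t2)))
  # single-decay spot value: PD 100, T2 50, TE 50 -> 100/e
  proto2 <- acquisition_protocol("MULTIECHO_T2", c(25, 50, 75), 600)
  s2 <- simulate_multiecho_series(block_map(rep(50, 4)), block_map(rep(100, 4)),
                                  proto2, noise_sigma = 0)
  expect_equal(s2$data[1, 1, 1, 2], 100 / exp(1))
})

test_that("background voxels carry the analytic Rician floor", {
  shp <- c(25, 25, 16)  # 10^4 voxels
  zero <- array(0, dim = shp)
  sigma <- 5
  proto <- acquisition_protocol("IR_T1", c(100, 200, 300), 1000)
  s <- simulate_ir_series(zero, zero, proto, noise_sigma = sigma, seed = 8)
  v <- s$data[, , , 1]
  mu <- sigma * sqrt(pi / 2)
  se <- sigma * sqrt(2 - pi / 2) / sqrt(length(v))
  expect_lt(abs(mean(v) - mu), 3 * se)
})

test_that("simulations are bit-reproducible in the seed", {
  ph <- small_phantom()
  a <- simulate_ir_series(ph$maps$t1_ms, ph$maps$proton_density,
                          noise_sigma = 10, seed = 3)
  b <- simulate_ir_series(ph$maps$t1_ms, ph$maps$proton_density,
                          noise_sigma = 10, seed = 3)
  c <- simulate_ir_series(ph$maps$t1_ms, ph$maps$proton_density,
                          noise_sigma = 10, seed = 4)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("center effects compose gain, bias field and noise as specified", {
  ph <- small_phantom()
  s <- simulate_multiecho_series(ph$maps$t2_ms, ph$maps$proton_density,
                                 noise_sigma = 0)
  expect_identical(apply_center_effect(s, center_effect(1, 0, 0))$data, s$data)
  expect_equal(apply_center_effect(s, center_effect(2, 0, 0))$data, 2 * s$data)
  # bias field's peak deviation from 1 equals the requested amplitude
  # (measured on an everywhere-positive series so the peak is observable)
  su <- image_series(array(100, dim = c(8, 8, 4, 3)),
                     acquisition_protocol("MULTIECHO_T2", c(10, 20, 30), 600))
  sb <- apply_center_effect(su, center_effect(1, 0.1, 0, seed = 2))
  expect_equal(max(abs(sb$data / su$data - 1)), 0.1, tolerance = 1e-6)
  expect_error(center_effect(gain = 0), "gain")
  expect_error(center_effect(bias_field_amplitude = 1), "amplitude")
})

test_that("global gain leaves fitted relaxation times unchanged", {
  t2 <- block_map(c(40, 60, 80, 110), shape = c(4, 4, 2))
  pd <- block_map(rep(1000, 4), shape = c(4, 4, 2))
  s <- simulate_multiecho_series(t2, pd, noise_sigma = 5, seed = 9)
  s3 <- apply_center_effect(s, center_effect(3, 0, 0))
  o <- fit_options(min_signal = 0)
  f1 <- fit_t2_map(s, o); f3 <- fit_t2_map(s3, o)
  expect_equal(f3$value_ms, f1$value_ms, tolerance = 1e-6)
  expect_equal(f3$amplitude, 3 * f1$amplitude, tolerance = 1e-6)
})

test_that("label perturbation is identity at zero and degrades Dice monotonically", {
  ph <- small_phantom()
  expect_identical(perturb_labels(ph$lv, 0, seed = 1)$labels, ph$lv$labels)
  p <- perturb_labels(ph$lv, 2, seed = 1)
  expect_identical(p$lut, ph$lv$lut)
  expect_true(all(setdiff(unique(as.integer(p$labels)), 0L) %in% p$lut$label_id))
  expect_identical(perturb_labels(ph$lv, 2, seed = 1)$labels, p$labels)

  mean_dice <- function(mag) {
    mean(sapply(1:10, function(sd) {
      q <- perturb_labels(ph$lv, mag, seed = sd)
      mean(sapply(ph$lv$lut$label_id, function(l) dice_score(ph$lv, q, l)))
    }))
  }
  d <- sapply(c(0.5, 1, 2, 4), mean_dice)
  expect_true(all(diff(d) < 0))
  expect_error(perturb_labels(ph$lv, -1), "magnitude")
})
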