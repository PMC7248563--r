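# Forward simulation of multicenter relaxometry acquisitions: noiseless
# signal models, Rician magnitude noise, per-center gain/bias-field/noise
# effects, and smooth label perturbation emulating inter-atlas variability.

# Rician-corrupt a non-negative signal array: the magnitude of the signal
# plus complex Gaussian noise, sqrt((s + n1)^2 + n2^2).  Caller controls the
# RNG state.
add_rician <- function(s, sigma) {
  if (sigma == 0) return(s)
  n <- length(s)
  array(sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2),
        dim = dim(s))
}

#' Simulate an inversion-recovery T1 series
#'
#' Noiseless voxel signal is `|PD * (1 - B * exp(-TI / T1))|` (magnitude
#' inversion recovery); Rician noise of scale `noise_sigma` is then applied,
#' so background voxels (PD = 0) carry the pure Rician noise floor with mean
#' `sigma * sqrt(pi / 2)`.
#'
#' @param t1_map,pd_map 3-D arrays of ground-truth T1 (ms) and proton
#'   density; voxels with `t1 <= 0` or `pd == 0` produce zero signal.
#' @param protocol An [acquisition_protocol()] with modality `"IR_T1"`.
#' @param inversion_efficiency The inversion factor B in (0, 2]; 2 is a
#'   perfect 180-degree inversion.
#' @param noise_sigma Rician noise scale in signal units (>= 0).
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @param voxel_size_um,affine Geometry passed to [image_series()].
#' @return An [image_series()].
#' @export
simulate_ir_series <- function(t1_map, pd_map, protocol = default_ir_protocol(),
                               inversion_efficiency = 2,
                               noise_sigma = 0, seed = 1L,
                               voxel_size_um = c(211, 211, 424),
                               affine = default_affine(voxel_size_um)) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (protocol$modality != "IR_T1")
    stop_relaxo("protocol modality is %s; IR_T1 required", protocol$modality)
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop_relaxo("noise_sigma must be >= 0")
  if (inversion_efficiency <= 0 || inversion_efficiency > 2)
    stop_relaxo("inversion_efficiency must be in (0, 2]")
  stopifnot(identical(dim(t1_map), dim(pd_map)), length(dim(t1_map)) == 3L)
  ti <- protocol$times_ms
  shp <- dim(t1_map)
  live <- t1_map > 0 & pd_map > 0
  t1s <- ifelse(live, t1_map, 1)  # placeholder to avoid division by zero
  out <- array(0, dim = c(shp, length(ti)))
  for (k in seq_along(ti)) {
    s <- abs(pd_map * (1 - inversion_efficiency * exp(-ti[k] / t1s)))
    s[!live] <- 0
    out[, , , k] <- s
  }
  out <- with_seed(seed, add_rician(out, noise_sigma))
  image_series(out, protocol, voxel_size_um = voxel_size_um, affine = affine)
}

#' Simulate a multi-echo T2 series
#'
#' Noiseless voxel signal is `PD * exp(-TE / T2)`; Rician noise as in
#' [simulate_ir_series()].
#'
#' @param t2_map,pd_map 3-D ground-truth arrays.
#' @param protocol An [acquisition_protocol()] with modality
#'   `"MULTIECHO_T2"`; default is the 28-echo 8..224 ms protocol.
#' @inheritParams simulate_ir_series
#' @return An [image_series()].
#' @export
simulate_multiecho_series <- function(t2_map, pd_map,
                                      protocol = default_multiecho_protocol(),
                                      noise_sigma = 0, seed = 1L,
                                      voxel_size_um = c(211, 211, 424),
                                      affine = default_affine(voxel_size_um)) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (protocol$modality != "MULTIECHO_T2")
    stop_relaxo("protocol modality is %s; MULTIECHO_T2 required", protocol$modality)
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop_relaxo("noise_sigma must be >= 0")
  stopifnot(identical(dim(t2_map), dim(pd_map)), length(dim(t2_map)) == 3L)
  te <- protocol$times_ms
  shp <- dim(t2_map)
  live <- t2_map > 0 & pd_map > 0
  t2s <- ifelse(live, t2_map, 1)
  out <- array(0, dim = c(shp, length(te)))
  for (k in seq_along(te)) {
    s <- pd_map * exp(-te[k] / t2s)
    s[!live] <- 0
    out[, , , k] <- s
  }
  out <- with_seed(seed, add_rician(out, noise_sigma))
  image_series(out, protocol, voxel_size_um = voxel_size_um, affine = affine)
}

#' Per-center acquisition effect
#'
#' A simple surrogate for the hardware differences between imaging centers
#' (transmit/receive coils, gradients): a global gain, a smooth
#' multiplicative bias field, and extra Rician noise.
#'
#' @param gain Global multiplicative factor (> 0).
#' @param bias_field_amplitude Peak relative deviation of the smooth
#'   multiplicative field from 1, in [0, 1).
#' @param noise_sigma Extra Rician noise scale (>= 0), in signal units.
#' @param seed Integer seed for the bias field and the noise.
#' @return An object of class `center_effect`.
#' @export
center_effect <- function(gain = 1, bias_field_amplitude = 0, noise_sigma = 0,
                          seed = 1L) {
  if (!is.numeric(gain) || gain <= 0) stop_relaxo("gain must be > 0")
  if (bias_field_amplitude < 0 || bias_field_amplitude >= 1)
    stop_relaxo("bias_field_amplitude must be in [0, 1)")
  if (noise_sigma < 0) stop_relaxo("noise_sigma must be >= 0")
  structure(list(gain = gain, bias_field_amplitude = bias_field_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "center_effect")
}

#' Apply a center effect to a series
#'
#' `out = series * gain * field`, where `field` is a smooth multiplicative
#' bias field normalized so its maximum deviation from 1 equals
#' `bias_field_amplitude`, followed by extra Rician noise.  The identity
#' effect (gain 1, amplitude 0, sigma 0) returns the input bit-identically.
#'
#' @param series An [image_series()].
#' @param effect A [center_effect()].
#' @return An [image_series()].
#' @export
apply_center_effect <- function(series, effect) {
  stopifnot(inherits(series, "image_series"), inherits(effect, "center_effect"))
  if (effect$gain == 1 && effect$bias_field_amplitude == 0 &&
      effect$noise_sigma == 0)
    return(series)
  shp <- dim(series$data)[1:3]
  dat <- with_seed(effect$seed, {
    field <- 1
    if (effect$bias_field_amplitude > 0) {
      f <- smooth_random_field(shp)
      field <- 1 + effect$bias_field_amplitude * f / max(abs(f))
    }
    d <- series$data * effect$gain
    if (!identical(field, 1)) d <- d * as.vector(field)  # recycled over t
    add_rician(d, effect$noise_sigma)
  })
  image_series(dat, series$protocol, voxel_size_um = series$voxel_size_um,
               affine = series$affine)
}

#' Perturb a parcellation through a smooth random displacement field
#'
#' Emulates the delineation/registration variability between the members of
#' a multi-atlas set: labels are pulled back through a smooth random
#' displacement field whose root-mean-square vector amplitude equals
#' `magnitude` voxels, with nearest-neighbour sampling.  `magnitude = 0` is
#' the identity; the lut is unchanged.
#'
#' @param lv A [label_volume()].
#' @param magnitude RMS displacement amplitude in voxels (>= 0).
#' @param seed Integer seed.
#' @return A [label_volume()] on the same grid and lut.
#' @export
perturb_labels <- function(lv, magnitude, seed = 1L) {
  stopifnot(inherits(lv, "label_volume"))
  if (!is.numeric(magnitude) || magnitude < 0)
    stop_relaxo("magnitude must be >= 0")
  if (magnitude == 0) return(lv)
  shp <- dim(lv$labels)
  disp <- with_seed(seed, {
    d <- lapply(1:3, function(i) smooth_random_field(shp))
    rms <- sqrt(mean(d[[1]]^2 + d[[2]]^2 + d[[3]]^2))
    lapply(d, function(f) f * magnitude / rms)
  })
  idx <- arrayInd(seq_along(lv$labels), shp)
  src <- sapply(1:3, function(i)
    pmin(shp[i], pmax(1L, as.integer(round(idx[, i] + disp[[i]])))))
  new <- array(lv$labels[cbind(src[, 1], src[, 2], src[, 3])], dim = shp)
  label_volume(new, lv$lut, voxel_size_um = lv$voxel_size_um, affine = lv$affine)
}
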