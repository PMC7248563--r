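# Digital rat-brain phantom: a schematic 29-region parcellation inside an
# ellipsoidal brain envelope, with piecewise-constant ground-truth T1/T2/PD.
#
# Geometry is deliberately schematic (seeded region growth inside an
# ellipsoid, not anatomy): downstream analyses only depend on region
# adjacency, size ratios (ventricles much smaller than parenchyma) and the
# truth values, not on anatomical shape.

# Approximate anatomical layout of region seed points, as fractions of the
# envelope semi-axes: x lateral (L negative), y anterior(+)/posterior(-),
# z superior(+)/inferior(-).  Bilateral structures are mirrored in x.
region_layout <- function() {
  pos <- rbind(
    "3rd and 4th ventricles"  = c(0.00, -0.30, -0.10),
    "Amygdala"                = c(0.60,  0.10, -0.45),
    "Caudate-putamen"         = c(0.45,  0.35, -0.10),
    "Cerebellum"              = c(0.30, -0.75,  0.10),
    "Cingulate cortex"        = c(0.12,  0.30,  0.55),
    "Cortical white matter"   = c(0.30,  0.00,  0.20),
    "Frontal cortex"          = c(0.45,  0.55,  0.30),
    "Hippocampus"             = c(0.35, -0.15,  0.00),
    "Lateral ventricle"       = c(0.25,  0.15,  0.10),
    "Occipital cortex"        = c(0.40, -0.45,  0.40),
    "Olfactory bulb"          = c(0.20,  0.85,  0.00),
    "Parietal cortex"         = c(0.50,  0.00,  0.50),
    "Temporal cortex"         = c(0.65, -0.10, -0.10),
    "Thalamus"                = c(0.15, -0.05, -0.15),
    "Brain stem"              = c(0.00, -0.60, -0.50),
    "Cerebellar white matter" = c(0.00, -0.75, -0.10))
  pos
}

# Ground-truth relaxation times (ms) and proton density at 7 T for each
# structure class; CSF-filled ventricles are long-T1/long-T2, white matter
# shortest.  Values sit inside the plausibility bounds (T1 <= 3000 ms,
# T2 <= 300 ms).
region_truth_defaults <- function() {
  base <- rbind(
    "3rd and 4th ventricles"  = c(2800, 180, 1.00),
    "Amygdala"                = c(1800,  44, 0.90),
    "Caudate-putamen"         = c(1750,  42, 0.90),
    "Cerebellum"              = c(1800,  43, 0.90),
    "Cingulate cortex"        = c(1900,  46, 0.92),
    "Cortical white matter"   = c(1550,  37, 0.85),
    "Frontal cortex"          = c(1880,  45, 0.92),
    "Hippocampus"             = c(1850,  45, 0.91),
    "Lateral ventricle"       = c(2750, 170, 1.00),
    "Occipital cortex"        = c(1860,  44, 0.92),
    "Olfactory bulb"          = c(1900,  48, 0.90),
    "Parietal cortex"         = c(1870,  45, 0.92),
    "Temporal cortex"         = c(1840,  44, 0.92),
    "Thalamus"                = c(1700,  40, 0.90),
    "Brain stem"              = c(1650,  39, 0.88),
    "Cerebellar white matter" = c(1500,  36, 0.85))
  colnames(base) <- c("t1_ms", "t2_ms", "proton_density")
  lut <- region_lut()
  structure_of <- sub(" [LR]$", "", lut$region_name)
  out <- data.frame(label_id = lut$label_id, region_name = lut$region_name,
                    t1_ms = base[structure_of, "t1_ms"],
                    t2_ms = base[structure_of, "t2_ms"],
                    proton_density = base[structure_of, "proton_density"],
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# Relative voxel-count targets per region class.  At full study resolution
# lateral ventricles hold ~3500 voxels, the 3rd-and-4th-ventricle
# compartment ~11000 and other structures ~33000 on average, giving ratios
# of roughly 0.106 and 0.333 relative to parenchyma.
default_size_ratios <- function() {
  c(ventricle_lateral = 3500 / 33000,
    ventricle_3rd4th = 11000 / 33000,
    white_matter = 1,
    parenchyma = 1)
}

#' Specification of the digital phantom
#'
#' @param grid_shape Three positive integers (x, y, z).
#' @param region_truth `data.frame` with columns `label_id`, `region_name`,
#'   `t1_ms`, `t2_ms`, `proton_density`; defaults give plausible 7 T rat
#'   values.  T1 must lie in (0, 3000] ms and T2 in (0, 300] ms.
#' @param target_size_ratios Named relative voxel-count targets per region
#'   class (see [region_lut()] classes).
#' @param proton_density_scale Signal scale applied to proton density when
#'   simulating, so that peak magnitude is about this value.
#' @param seed Integer seed controlling jitter of the region seed points.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 32),
                         region_truth = region_truth_defaults(),
                         target_size_ratios = default_size_ratios(),
                         proton_density_scale = 1000,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop_relaxo("grid_shape must be 3 positive integers")
  region_truth <- as.data.frame(region_truth, stringsAsFactors = FALSE)
  need <- c("label_id", "region_name", "t1_ms", "t2_ms", "proton_density")
  if (!all(need %in% names(region_truth)))
    stop_relaxo("region_truth must have columns %s", paste(need, collapse = ", "))
  if (nrow(region_truth) != 29L)
    stop_relaxo("region_truth must describe exactly 29 regions, got %d",
                nrow(region_truth))
  bad_t1 <- region_truth$t1_ms <= 0 | region_truth$t1_ms > 3000
  bad_t2 <- region_truth$t2_ms <= 0 | region_truth$t2_ms > 300
  if (any(bad_t1))
    stop_relaxo("t1_ms out of (0, 3000] for region(s): %s",
                paste(region_truth$region_name[bad_t1], collapse = ", "))
  if (any(bad_t2))
    stop_relaxo("t2_ms out of (0, 300] for region(s): %s",
                paste(region_truth$region_name[bad_t2], collapse = ", "))
  if (any(region_truth$proton_density < 0))
    stop_relaxo("proton_density must be >= 0")
  stopifnot(is_count(seed + 1))  # allow 0
  structure(list(grid_shape = grid_shape, region_truth = region_truth,
                 target_size_ratios = target_size_ratios,
                 proton_density_scale = proton_density_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the 29-region label phantom
#'
#' Voxels inside an ellipsoidal brain envelope are partitioned among the 29
#' regions by quota-constrained nearest-seed growth: each region has a
#' target voxel count proportional to its class size ratio, seed points sit
#' at fixed (slightly seed-jittered) anatomical-like positions, and voxels
#' are claimed in order of increasing distance by regions that still have
#' remaining quota.  The result is deterministic for a given spec and seed,
#' has exactly 29 nonzero labels, and realizes the requested size ratios up
#' to rounding (each region is guaranteed at least 8 voxels).
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()] whose `lut` is [region_lut()].
#' @export
make_label_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$grid_shape
  lut <- region_lut()

  # ellipsoid envelope
  semi <- pmax(shp * c(0.45, 0.47, 0.45), 1)
  ctr <- (shp + 1) / 2
  ax <- (seq_len(shp[1]) - ctr[1]) / semi[1]
  ay <- (seq_len(shp[2]) - ctr[2]) / semi[2]
  az <- (seq_len(shp[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  inside <- which(r2 <= 1)
  n_in <- length(inside)
  if (n_in < 29L * 8L)
    stop_relaxo("grid %s too small: envelope has %d voxels, need >= %d",
                paste(shp, collapse = "x"), n_in, 29L * 8L)

  # per-region quotas from class ratios, floored at 8 voxels
  w <- spec$target_size_ratios[lut$class]
  quota <- pmax(8L, as.integer(round(w / sum(w) * n_in)))
  # trim rounding excess from the largest regions so sum(quota) <= n_in
  excess <- sum(quota) - n_in
  while (excess > 0L) {
    i <- which.max(quota)
    take <- min(excess, quota[i] - 8L)
    if (take <= 0L) stop_relaxo("grid too small to place regions: %s",
                                paste(lut$region_name[quota <= 8L], collapse = ", "))
    quota[i] <- quota[i] - take
    excess <- excess - take
  }
  quota[which.max(quota)] <- quota[which.max(quota)] + (n_in - sum(quota))

  # seed points in normalized envelope coordinates, mirrored for L/R
  lay <- region_layout()
  structure_of <- sub(" [LR]$", "", lut$region_name)
  pts <- lay[structure_of, , drop = FALSE]
  pts[lut$hemisphere == "L", 1] <- -pts[lut$hemisphere == "L", 1]
  jit <- with_seed(spec$seed, matrix(stats::runif(29 * 3, -0.05, 0.05), 29, 3))
  pts <- pts * 0.92 + jit  # shrink toward centre so seeds stay inside

  # voxel coordinates (normalized) of envelope voxels
  idx <- arrayInd(inside, shp)
  vox <- cbind((idx[, 1] - ctr[1]) / semi[1],
               (idx[, 2] - ctr[2]) / semi[2],
               (idx[, 3] - ctr[3]) / semi[3])

  # distances voxel x region, then greedy quota-constrained assignment in
  # global order of increasing distance
  d2 <- matrix(0, n_in, 29L)
  for (r in 1:29)
    d2[, r] <- (vox[, 1] - pts[r, 1])^2 + (vox[, 2] - pts[r, 2])^2 +
               (vox[, 3] - pts[r, 3])^2
  ord <- order(d2)  # column-major: pair (voxel, region)
  assigned <- integer(n_in)
  remaining <- quota
  n_left <- n_in
  vi_all <- ((ord - 1L) %% n_in) + 1L
  ri_all <- ((ord - 1L) %/% n_in) + 1L
  for (k in seq_along(ord)) {
    vi <- vi_all[k]
    if (assigned[vi] != 0L) next
    ri <- ri_all[k]
    if (remaining[ri] == 0L) next
    assigned[vi] <- ri
    remaining[ri] <- remaining[ri] - 1L
    n_left <- n_left - 1L
    if (n_left == 0L) break
  }

  labels <- array(0L, dim = shp)
  labels[inside] <- lut$label_id[assigned]
  label_volume(labels, lut)
}

#' Piecewise-constant ground-truth maps from a label phantom
#'
#' @param labels A [label_volume()].
#' @param spec The [phantom_spec()] providing per-region truth values.
#' @return A list with 3-D arrays `t1_ms`, `t2_ms`, `proton_density`
#'   (background voxels are 0 in all three).
#' @export
truth_maps <- function(labels, spec) {
  stopifnot(inherits(labels, "label_volume"), inherits(spec, "phantom_spec"))
  present <- setdiff(unique(as.integer(labels$labels)), 0L)
  missing <- setdiff(present, spec$region_truth$label_id)
  if (length(missing) > 0L)
    stop_relaxo("no truth entry for label(s): %s", paste(missing, collapse = ", "))
  mk <- function(col, scale = 1) {
    v <- c(0, spec$region_truth[[col]] * scale)
    key <- match(as.integer(labels$labels), c(0L, spec$region_truth$label_id))
    array(v[key], dim = dim(labels$labels))
  }
  list(t1_ms = mk("t1_ms"), t2_ms = mk("t2_ms"),
       proton_density = mk("proton_density", spec$proton_density_scale))
}
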