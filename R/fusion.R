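# Multi-atlas maximum-probability label fusion and overlap metrics.

#' Bundle co-registered atlas label volumes
#'
#' @param atlases List of [label_volume()] objects sharing one grid shape
#'   and one lut.
#' @return An object of class `atlas_set`.
#' @export
atlas_set <- function(atlases) {
  if (!is.list(atlases) || length(atlases) < 1L)
    stop_relaxo("atlas_set needs at least one atlas")
  if (!all(vapply(atlases, inherits, TRUE, "label_volume")))
    stop_relaxo("all atlases must be label_volume objects")
  shp <- dim(atlases[[1]]$labels)
  lut <- atlases[[1]]$lut
  for (i in seq_along(atlases)) {
    if (!identical(dim(atlases[[i]]$labels), shp))
      stop_relaxo("atlas %d grid %s differs from %s", i,
                  paste(dim(atlases[[i]]$labels), collapse = "x"),
                  paste(shp, collapse = "x"))
    if (!identical(atlases[[i]]$lut[c("label_id", "region_name", "hemisphere")],
                   lut[c("label_id", "region_name", "hemisphere")]))
      stop_relaxo("atlas %d lut differs from atlas 1", i)
  }
  structure(list(atlases = atlases, n_atlases = length(atlases)),
            class = "atlas_set")
}

#' Maximum-probability label fusion
#'
#' Per-voxel plurality vote over the hard labels of all atlases (the label
#' probability at a voxel is its vote fraction, so the most probable label
#' is the most voted one).  Background (0) participates as a candidate.
#' Ties are broken deterministically towards the smallest label id, and the
#' result is therefore invariant under atlas reordering.
#'
#' @param atlases An [atlas_set()] (or a plain list of [label_volume()]).
#' @return A fused [label_volume()] on the shared grid and lut.
#' @export
fuse_max_probability <- function(atlases) {
  if (!inherits(atlases, "atlas_set")) atlases <- atlas_set(atlases)
  first <- atlases$atlases[[1]]
  shp <- dim(first$labels)
  cand <- sort(unique(unlist(lapply(atlases$atlases,
                                    function(a) unique(as.integer(a$labels))))))
  best <- array(cand[1], dim = shp)
  bestcount <- Reduce(`+`, lapply(atlases$atlases,
                                  function(a) a$labels == cand[1]))
  for (l in cand[-1]) {
    cnt <- Reduce(`+`, lapply(atlases$atlases, function(a) a$labels == l))
    upd <- cnt > bestcount  # strict: earlier (smaller) label wins ties
    best[upd] <- l
    bestcount[upd] <- cnt[upd]
  }
  label_volume(best, first$lut, voxel_size_um = first$voxel_size_um,
               affine = first$affine)
}

#' Dice overlap of one label between two parcellations
#'
#' `2 |A n B| / (|A| + |B|)` for the binary masks of `label_id`.  Two empty
#' masks give 1 (a region absent from both parcellations is in perfect
#' agreement; the 0/0 case must be defined explicitly).
#'
#' @param a,b [label_volume()] objects on the same grid.
#' @param label_id The label to compare.
#' @return Dice coefficient in [0, 1].
#' @export
dice_score <- function(a, b, label_id) {
  stopifnot(inherits(a, "label_volume"), inherits(b, "label_volume"))
  if (!identical(dim(a$labels), dim(b$labels)))
    stop_relaxo("grid mismatch: %s vs %s",
                paste(dim(a$labels), collapse = "x"),
                paste(dim(b$labels), collapse = "x"))
  ma <- a$labels == label_id
  mb <- b$labels == label_id
  denom <- sum(ma) + sum(mb)
  if (denom == 0L) return(1)
  2 * sum(ma & mb) / denom
}

#' Per-region voxel counts and volumes
#'
#' @param lv A [label_volume()].
#' @return A `data.frame` with one row per lut entry: `label_id`,
#'   `region_name`, `voxel_count` (0 allowed) and `volume_mm3`
#'   (count x voxel volume).
#' @export
parcel_volumes <- function(lv) {
  stopifnot(inherits(lv, "label_volume"))
  tab <- tabulate(as.integer(lv$labels), nbins = max(lv$lut$label_id))
  count <- tab[lv$lut$label_id]
  vox_mm3 <- prod(lv$voxel_size_um / 1000)
  data.frame(label_id = lv$lut$label_id, region_name = lv$lut$region_name,
             voxel_count = count, volume_mm3 = count * vox_mm3,
             stringsAsFactors = FALSE)
}
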