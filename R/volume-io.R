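# File interchange: NIfTI-1 volumes, JSON timing sidecars, TSV label tables.
#
# Conventions: signal and parameter maps are stored as 32-bit float, labels
# as unsigned 16-bit integers; voxel indices are 0-based on disk (NIfTI),
# world coordinates come from the stored affine; no reorientation is ever
# performed (volumes are assumed co-registered upstream).

sidecar_keys <- c("modality", "times_ms", "tr_ms")

read_sidecar <- function(path) {
  if (!file.exists(path)) stop_relaxo("sidecar file not found: %s", path)
  sc <- jsonlite::fromJSON(path)
  for (k in sidecar_keys)
    if (is.null(sc[[k]])) stop_relaxo("sidecar %s is missing key '%s'", path, k)
  sc
}

write_sidecar <- function(protocol, path) {
  jsonlite::write_json(list(modality = protocol$modality,
                            times_ms = protocol$times_ms,
                            tr_ms = protocol$tr_ms),
                       path, auto_unbox = TRUE, digits = NA)
}

nifti_affine <- function(img) {
  x <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(x, "try-error")) return(diag(4))
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x[1:4, 1:4]
}

nifti_voxel_um <- function(img) {
  p <- attr(img, "pixdim")
  if (is.null(p)) p <- RNifti::pixdim(img)
  as.numeric(p[1:3]) * 1000  # NIfTI pixdim assumed mm
}

#' Read a 4-D magnitude series and its timing sidecar
#'
#' @param volume_path 4-D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param sidecar_path JSON file with keys `modality`, `times_ms`, `tr_ms`
#'   (milliseconds).
#' @return A validated [image_series()].
#' @export
read_series <- function(volume_path, sidecar_path) {
  img <- RNifti::readNifti(volume_path)
  sc <- read_sidecar(sidecar_path)
  protocol <- acquisition_protocol(sc$modality, sc$times_ms, sc$tr_ms)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop_relaxo("%s is %d-D; a 4-D series is required", volume_path, length(dim(arr)))
  if (dim(arr)[4] != length(protocol$times_ms))
    stop_relaxo("volume has %d time frames but sidecar lists %d times",
                dim(arr)[4], length(protocol$times_ms))
  image_series(array(as.numeric(arr), dim = dim(arr)), protocol,
               voxel_size_um = nifti_voxel_um(img), affine = nifti_affine(img))
}

#' Write a series as NIfTI-1 (32-bit float) plus a JSON sidecar
#'
#' @param series An [image_series()].
#' @param volume_path,sidecar_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_series <- function(series, volume_path, sidecar_path) {
  if (!inherits(series, "image_series")) stop_relaxo("series must be an image_series")
  if (any(dim(series$data) == 0L)) stop_relaxo("refusing to write empty-extent series")
  if (any(!is.finite(series$data)))
    stop_relaxo("refusing to write series containing non-finite values")
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size_um / 1000, 1)  # 4th dim: frame index
  RNifti::writeNifti(img, volume_path, datatype = "float")
  write_sidecar(series$protocol, sidecar_path)
  invisible(c(volume_path, sidecar_path))
}

#' Read a parcellation volume and its label lookup table
#'
#' @param volume_path Integer-valued 3-D NIfTI-1 file.
#' @param lut_path Tab-separated table with header
#'   `label_id  region_name  hemisphere`.
#' @return A validated [label_volume()].
#' @export
read_labels <- function(volume_path, lut_path) {
  img <- RNifti::readNifti(volume_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop_relaxo("%s is %d-D; a 3-D label volume is required",
                volume_path, length(dim(arr)))
  if (any(arr != round(arr)))
    stop_relaxo("%s contains non-integer voxel values", volume_path)
  lut <- utils::read.delim(lut_path, stringsAsFactors = FALSE)
  label_volume(array(as.integer(arr), dim = dim(arr)), lut,
               voxel_size_um = nifti_voxel_um(img), affine = nifti_affine(img))
}

#' Write a parcellation as NIfTI-1 (unsigned 16-bit) plus a TSV lut
#'
#' @param lv A [label_volume()].
#' @param volume_path,lut_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_labels <- function(lv, volume_path, lut_path) {
  if (!inherits(lv, "label_volume")) stop_relaxo("lv must be a label_volume")
  if (max(lv$labels) > 65535L) stop_relaxo("label ids exceed unsigned 16-bit range")
  img <- RNifti::asNifti(lv$labels)
  RNifti::pixdim(img) <- lv$voxel_size_um / 1000
  RNifti::writeNifti(img, volume_path, datatype = "uint16")
  utils::write.table(lv$lut[c("label_id", "region_name", "hemisphere")],
                     lut_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(volume_path, lut_path))
}

#' Write a 3-D scalar map (e.g. a fitted parameter map) as 32-bit NIfTI
#' @param map 3-D numeric array.
#' @param path Output path.
#' @param voxel_size_um Length-3 voxel size in micrometres.
#' @return Invisibly, the path.
#' @export
write_map <- function(map, path, voxel_size_um = c(211, 211, 424)) {
  stopifnot(is.array(map), length(dim(map)) == 3L)
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- voxel_size_um / 1000
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
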