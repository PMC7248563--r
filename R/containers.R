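# In-memory containers: 4-D magnitude series and 3-D integer parcellations.

default_affine <- function(voxel_size_um) {
  a <- diag(c(voxel_size_um / 1000, 1))  # voxel index -> mm
  a
}

#' 4-D magnitude image series
#'
#' A non-negative 4-D array `(x, y, z, t)` of magnitude MR signal, its
#' acquisition protocol and voxel geometry.  The fourth dimension must match
#' the protocol's number of sampling times.
#'
#' @param data 4-D numeric array, finite and non-negative (magnitude data).
#' @param protocol An [acquisition_protocol()].
#' @param voxel_size_um Length-3 positive vector, voxel edge lengths in
#'   micrometres.  Default is the study resolution 211 x 211 x 424 um.
#' @param affine 4 x 4 voxel-to-world matrix; defaults to a scaling by the
#'   voxel size (mm).
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, protocol,
                         voxel_size_um = c(211, 211, 424),
                         affine = default_affine(voxel_size_um)) {
  if (!inherits(protocol, "acquisition_protocol"))
    stop_relaxo("protocol must be an acquisition_protocol")
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_relaxo("data must be a 4-D array, got %s dims",
                paste(length(dim(data)), collapse = "x"))
  d <- dim(data)
  if (any(d == 0L)) stop_relaxo("data has an empty extent: %s", paste(d, collapse = "x"))
  nt <- length(protocol$times_ms)
  if (d[4] != nt)
    stop_relaxo("4th dimension (%d volumes) does not match protocol (%d times)",
                d[4], nt)
  if (any(!is.finite(data)))
    stop_relaxo("data contains non-finite values; magnitude data must be finite")
  if (any(data < 0))
    stop_relaxo("data contains negative values; magnitude data must be >= 0")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop_relaxo("voxel_size_um must be 3 positive numbers")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop_relaxo("affine must be 4x4")
  structure(list(data = data, protocol = protocol,
                 voxel_size_um = voxel_size_um, affine = affine),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("<image_series> %s grid, %s, voxels %s um\n",
              paste(dim(x$data), collapse = "x"), x$protocol$modality,
              paste(x$voxel_size_um, collapse = "x")))
  invisible(x)
}

#' 3-D integer parcellation with a label lookup table
#'
#' @param labels 3-D array of non-negative integers; 0 is background.
#' @param lut `data.frame` with columns `label_id` (unique positive
#'   integers), `region_name`, `hemisphere` (one of `"L"`, `"R"`, `"none"`).
#'   Every nonzero label present in `labels` must appear in `lut`.
#' @param voxel_size_um,affine As for [image_series()].
#' @return An object of class `label_volume`.
#' @seealso [region_lut()] for the canonical 29-region table.
#' @export
label_volume <- function(labels, lut,
                         voxel_size_um = c(211, 211, 424),
                         affine = default_affine(voxel_size_um)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop_relaxo("labels must be a 3-D array")
  if (any(dim(labels) == 0L)) stop_relaxo("labels has an empty extent")
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels)))
    stop_relaxo("labels must be non-negative integers")
  lut <- as.data.frame(lut, stringsAsFactors = FALSE)
  need <- c("label_id", "region_name", "hemisphere")
  if (!all(need %in% names(lut)))
    stop_relaxo("lut must have columns %s", paste(need, collapse = ", "))
  lut$label_id <- as.integer(lut$label_id)
  if (anyDuplicated(lut$label_id) || any(lut$label_id <= 0))
    stop_relaxo("lut label ids must be unique and > 0")
  if (!all(lut$hemisphere %in% c("L", "R", "none")))
    stop_relaxo("lut hemisphere must be 'L', 'R' or 'none'")
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, lut$label_id)
  if (length(missing) > 0L)
    stop_relaxo("labels present in grid but absent from lut: %s",
                paste(sort(missing), collapse = ", "))
  storage.mode(labels) <- "integer"
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop_relaxo("voxel_size_um must be 3 positive numbers")
  structure(list(labels = labels, lut = lut,
                 voxel_size_um = voxel_size_um, affine = as.matrix(affine)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s grid, %d lut regions, %d present\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$lut),
              length(setdiff(unique(as.integer(x$labels)), 0L))))
  invisible(x)
}

#' Canonical 29-region rat-brain lookup table
#'
#' Thirteen bilateral structures (left/right) plus three non-lateralized
#' ones: the 3rd-and-4th-ventricle compartment, the brain stem and the
#' cerebellar white matter.
#'
#' @return A `data.frame` with columns `label_id`, `region_name`,
#'   `hemisphere` and `class` (`"ventricle_lateral"`, `"ventricle_3rd4th"`,
#'   `"white_matter"`, `"parenchyma"`), 29 rows.
#' @export
region_lut <- function() {
  bilateral <- c("Amygdala", "Caudate-putamen", "Cerebellum",
                 "Cingulate cortex", "Cortical white matter", "Frontal cortex",
                 "Hippocampus", "Lateral ventricle", "Occipital cortex",
                 "Olfactory bulb", "Parietal cortex", "Temporal cortex",
                 "Thalamus")
  name <- c("3rd and 4th ventricles",
            as.vector(rbind(paste(bilateral, "L"), paste(bilateral, "R"))),
            "Brain stem", "Cerebellar white matter")
  hemi <- c("none", rep(c("L", "R"), times = length(bilateral)), "none", "none")
  cls <- rep("parenchyma", length(name))
  cls[name == "3rd and 4th ventricles"] <- "ventricle_3rd4th"
  cls[grepl("^Lateral ventricle", name)] <- "ventricle_lateral"
  cls[grepl("white matter", name)] <- "white_matter"
  data.frame(label_id = seq_along(name), region_name = name,
             hemisphere = hemi, class = cls, stringsAsFactors = FALSE)
}
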