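MODALITIES <- c("T1", "T1c", "T2", "FLAIR", "SEG")

# BraTS-conformant volume geometry (1 mm isotropic, 240 x 240 x 155)
BRATS_DIM <- c(240L, 240L, 155L)

#' MRI volume container
#'
#' A light container for a 3D voxel grid with modality and provenance.
#' Volumes whose grid is not the conformant 240 x 240 x 155 BraTS geometry
#' are accepted but carried with `conformant = FALSE`.
#'
#' @param voxels 3D numeric array (rows x cols x slices); all values finite.
#' @param modality one of `"T1"`, `"T1c"`, `"T2"`, `"FLAIR"`, `"SEG"`.
#' @param spacing numeric length-3, mm per voxel axis.
#' @param source_id free-text identifier (usually the file path).
#' @return an object of class `mri_volume`.
#' @export
mri_volume <- function(voxels, modality = "FLAIR", spacing = c(1, 1, 1),
                       source_id = "") {
  modality <- match.arg(modality, MODALITIES)
  if (length(dim(voxels)) == 2) {
    voxels <- array(voxels, dim = c(dim(voxels), 1L))
  }
  if (length(dim(voxels)) != 3) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  n_bad <- sum(!is.finite(voxels))
  if (n_bad > 0) {
    stop(sprintf("volume contains %d non-finite voxel(s)", n_bad),
         call. = FALSE)
  }
  structure(
    list(voxels = voxels, modality = modality,
         spacing = as.numeric(spacing), source_id = source_id,
         conformant = identical(dim(voxels), BRATS_DIM)),
    class = "mri_volume"
  )
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mri_volume> %s  %d x %d x %d%s  [%s]\n", x$modality,
              d[1], d[2], d[3], if (x$conformant) "" else " (non-conformant)",
              x$source_id))
  invisible(x)
}

#' 2D slice container
#'
#' @param pixels numeric matrix, all values finite.
#' @param modality MRI modality tag.
#' @param volume_id identifier of the source volume.
#' @param slice_index 0-based axial index in the source volume.
#' @return an object of class `slice2d`.
#' @export
slice2d <- function(pixels, modality = "FLAIR", volume_id = "",
                    slice_index = 0L) {
  stopifnot(is.matrix(pixels))
  if (any(!is.finite(pixels))) {
    stop("slice contains non-finite pixels", call. = FALSE)
  }
  if (slice_index < 0) stop("slice_index must be >= 0", call. = FALSE)
  structure(
    list(pixels = pixels, modality = match.arg(modality, MODALITIES),
         volume_id = volume_id, slice_index = as.integer(slice_index)),
    class = "slice2d"
  )
}

#' @export
print.slice2d <- function(x, ...) {
  cat(sprintf("<slice2d> %s  %d x %d  slice %d  [%s]\n", x$modality,
              nrow(x$pixels), ncol(x$pixels), x$slice_index, x$volume_id))
  invisible(x)
}

#' @export
dim.slice2d <- function(x) dim(x$pixels)

#' Feature-map stack
#'
#' Post-ReLU feature maps of the last convolution layer, stored as an
#' `H x W x K` array (`32 x 32 x 32` for the full-width network).
#'
#' @param maps 3D non-negative array, all maps the same square shape.
#' @return an object of class `feature_stack` (a classed array).
#' @export
feature_stack <- function(maps) {
  stopifnot(length(dim(maps)) == 3)
  if (any(!is.finite(maps))) stop("non-finite feature values", call. = FALSE)
  if (any(maps < 0)) stop("feature maps must be non-negative (post-ReLU)",
                          call. = FALSE)
  structure(maps, class = c("feature_stack", "array"))
}

n_maps <- function(f) dim(f)[3]

#' Saliency map
#'
#' Single grayscale localization map in `[0, 1]`.
#'
#' @param gray numeric matrix with values in `[0, 1]`.
#' @param source_shape optional original shape metadata.
#' @return an object of class `saliency_map` (a classed matrix).
#' @export
saliency_map <- function(gray, source_shape = dim(gray)) {
  stopifnot(is.matrix(gray))
  if (any(!is.finite(gray))) stop("non-finite saliency values", call. = FALSE)
  if (min(gray) < 0 || max(gray) > 1) {
    stop("saliency values must lie in [0, 1]", call. = FALSE)
  }
  structure(gray, class = c("saliency_map", "matrix"),
            source_shape = source_shape)
}

#' Binary segmentation mask
#'
#' @param mask matrix of 0/1 values aligned with the slice it annotates.
#' @param threshold_used the grayscale threshold that produced the mask.
#' @param provenance `"sweep"` or `"fixed"`.
#' @return an object of class `seg_mask` (a classed integer matrix).
#' @export
seg_mask <- function(mask, threshold_used = NA_real_,
                     provenance = c("fixed", "sweep")) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 1))) {
    stop("mask values must be 0 or 1", call. = FALSE)
  }
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  structure(m, class = c("seg_mask", "matrix"),
            threshold_used = threshold_used,
            provenance = match.arg(provenance))
}

# plain 0/1 integer matrix from a seg_mask or logical/numeric matrix
as_binary_matrix <- function(m) {
  stopifnot(is.matrix(m))
  out <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  out
}
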