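#' Read a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into an [mri_volume()].  Volumes with
#' the conformant BraTS geometry (240 x 240 x 155, 1 mm isotropic) are
#' marked `conformant = TRUE`; other shapes are accepted and flagged.
#'
#' @param path path to a NIfTI-1 file.
#' @param modality modality tag to record (`"FLAIR"`, `"SEG"`, ...).
#' @return an [mri_volume()].
#' @export
load_nifti_volume <- function(path, modality = "FLAIR") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop(sprintf("not a readable NIfTI file: %s (%s)",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  vox <- as.array(img)
  n_nan <- sum(is.nan(vox))
  if (n_nan > 0) {
    stop(sprintf("volume contains %d NaN voxel(s): %s", n_nan, path),
         call. = FALSE)
  }
  spacing <- tryCatch(RNifti::pixdim(img)[seq_len(min(3, length(dim(vox))))],
                      error = function(e) rep(1, 3))
  mri_volume(vox, modality = modality, spacing = spacing, source_id = path)
}

#' Write a volume to NIfTI
#'
#' @param vol an [mri_volume()] or 3D array.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path) {
  vox <- if (inherits(vol, "mri_volume")) vol$voxels else vol
  RNifti::writeNifti(RNifti::asNifti(vox), path)
  invisible(path)
}

#' Extract an axial slice
#'
#' Slice indexing is 0-based: slice 90 of a 155-slice volume is
#' `index = 90` with valid indices `0 .. 154`.
#'
#' @param vol an [mri_volume()].
#' @param index 0-based slice index (default 90, the mid-tumor plane
#'   conventionally used for 155-slice volumes).
#' @return a [slice2d()].
#' @export
extract_slice <- function(vol, index = 90L) {
  stopifnot(inherits(vol, "mri_volume"))
  n_slices <- dim(vol$voxels)[3]
  if (index < 0 || index >= n_slices) {
    stop(sprintf("slice index %d out of range [0, %d]", index, n_slices - 1),
         call. = FALSE)
  }
  slice2d(vol$voxels[, , index + 1L], modality = vol$modality,
          volume_id = vol$source_id, slice_index = index)
}

#' Centered crop of a slice
#'
#' Crops the central `rows x cols` window (default 192 x 152, which trims
#' the empty margins of a 240 x 240 brain slice).  No interpolation: output
#' pixels are a subset of input pixels.
#'
#' @param s a [slice2d()] or matrix.
#' @param rows,cols target size; must not exceed the slice size.
#' @return same container type as `s`.
#' @export
crop_slice <- function(s, rows = 192L, cols = 152L) {
  px <- pixels_of(s)
  if (rows > nrow(px) || cols > ncol(px)) {
    stop(sprintf("crop %d x %d exceeds slice %d x %d", rows, cols,
                 nrow(px), ncol(px)), call. = FALSE)
  }
  r0 <- floor((nrow(px) - rows) / 2)
  c0 <- floor((ncol(px) - cols) / 2)
  rewrap(s, px[r0 + seq_len(rows), c0 + seq_len(cols), drop = FALSE])
}

#' Resize a slice to the network input geometry
#'
#' Bilinear resample to `side x side` (default 128, the input size the
#' layer stack is dimensioned for).  Resizing to the current size is an
#' exact identity.
#'
#' @param s a [slice2d()] or matrix.
#' @param side target side length in pixels, at least 8.
#' @return same container type as `s`.
#' @export
resize_to_input <- function(s, side = 128L) {
  if (side < 8) stop("side must be >= 8", call. = FALSE)
  px <- pixels_of(s)
  rewrap(s, resize_bilinear(px, side, side))
}

#' Read a dataset manifest
#'
#' A manifest CSV maps image paths to modality and (optionally) a
#' segmentation path, one row per volume.  Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path manifest CSV with columns `image`, and optionally
#'   `modality`, `mask`, `label`, `seed`.
#' @return a tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  }
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!"image" %in% names(df)) {
    stop("manifest must have an `image` column", call. = FALSE)
  }
  base <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", df$image)
  df$image[rel] <- file.path(base, df$image[rel])
  if ("mask" %in% names(df)) {
    has <- !is.na(df$mask) & nzchar(df$mask)
    relm <- has & !grepl("^(/|[A-Za-z]:)", df$mask)
    df$mask[relm] <- file.path(base, df$mask[relm])
  }
  df
}
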