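#' Phantom specification
#'
#' Parameters of the synthetic FLAIR-like 2D phantom: a roughly
#' elliptical bright "brain" on a dark background with smooth texture
#' and noise, and (with probability `tumor_prob`) a single compact
#' hyperintense lesion whose mean intensity sits `lesion_contrast`
#' tissue standard deviations above the tissue mean — the hyperintense
#' tumor-plus-edema appearance the segmentation method assumes.
#'
#' @param side image side in pixels (default 128, the network input).
#' @param tumor_prob probability that a phantom carries a lesion.
#' @param lesion_radius_range min/max lesion semi-axis in pixels.
#' @param lesion_contrast lesion amplitude in multiples of the tissue
#'   standard deviation (default 3).
#' @param tissue_noise_sigma per-pixel Gaussian noise, intensity units.
#' @param blur_sigma edge-smoothing blur in pixels.
#' @param brain_axes_frac range of brain semi-axes as a fraction of the
#'   image side (default 0.70-0.85).
#' @param seed default seed for [generate_phantom()].
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 128L, tumor_prob = 0.5,
                         lesion_radius_range = c(6, 20),
                         lesion_contrast = 3.0,
                         tissue_noise_sigma = 0.05,
                         blur_sigma = 1.0,
                         brain_axes_frac = c(0.70, 0.85),
                         seed = 1L) {
  stopifnot(side >= 32, tumor_prob >= 0, tumor_prob <= 1,
            length(lesion_radius_range) == 2,
            lesion_radius_range[1] > 0,
            lesion_radius_range[2] < side / 2,
            lesion_contrast > 0, tissue_noise_sigma >= 0, blur_sigma >= 0)
  structure(list(side = as.integer(side), tumor_prob = tumor_prob,
                 lesion_radius_range = lesion_radius_range,
                 lesion_contrast = lesion_contrast,
                 tissue_noise_sigma = tissue_noise_sigma,
                 blur_sigma = blur_sigma,
                 brain_axes_frac = brain_axes_frac,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# filled ellipse indicator on an n x n grid
ellipse_mask <- function(n, cx, cy, a, b) {
  xr <- (row(matrix(0, n, n)) - cx) / a
  yc <- (col(matrix(0, n, n)) - cy) / b
  (xr^2 + yc^2 <= 1) * 1L
}

#' Generate one phantom slice
#'
#' Deterministic given `(spec, seed)`.  Returns the image as a
#' [slice2d()], the binary lesion mask (empty when no lesion was drawn)
#' and the tumor/not-tumor label derived from the mask via
#' [derive_labels()].
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return list with `slice`, `mask`, `label` and `lesion_area_px`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  n <- spec$side
  ctr <- n / 2 + 0.5

  # brain: centered ellipse with small jitter, soft edge
  ba <- runif(2, spec$brain_axes_frac[1], spec$brain_axes_frac[2]) * n / 2
  bc <- ctr + runif(2, -2, 2)
  brain <- ellipse_mask(n, bc[1], bc[2], ba[1], ba[2])
  brain_soft <- pixels_of(gaussian_blur(brain + 0, max(spec$blur_sigma, 0.5)))

  # tissue: base intensity + smooth low-frequency texture + pixel noise.
  # The texture stays well below the lesion contrast so that, as in real
  # FLAIR, the lesion is the conspicuously brightest structure.
  coarse <- matrix(rnorm(8 * 8, 0, 0.03), 8, 8)
  texture <- resize_bilinear(coarse, n, n)
  tissue <- 0.55 + texture +
    matrix(rnorm(n * n, 0, spec$tissue_noise_sigma), n, n)
  img <- tissue * brain_soft

  mask <- matrix(0L, n, n)
  if (runif(1) < spec$tumor_prob) {
    rr <- runif(2, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
    rmax <- max(rr)
    # rejection-sample a center so the lesion fits inside the brain
    cx <- bc[1]; cy <- bc[2]
    for (try in 1:200) {
      px <- runif(1, rmax + 2, n - rmax - 2)
      py <- runif(1, rmax + 2, n - rmax - 2)
      if (((px - bc[1]) / (ba[1] - rmax - 1))^2 +
          ((py - bc[2]) / (ba[2] - rmax - 1))^2 <= 1) {
        cx <- px; cy <- py
        break
      }
    }
    mask <- ellipse_mask(n, cx, cy, rr[1], rr[2])
    amp <- spec$lesion_contrast * sd(tissue[brain == 1])
    bump <- pixels_of(gaussian_blur(mask + 0, 1.5))
    img <- img + amp * bump
  }

  lbl <- derive_labels(list(mask))
  vol_id <- sprintf("phantom-%010d", seed)
  list(slice = slice2d(img, modality = "FLAIR", volume_id = vol_id,
                       slice_index = 0L),
       mask = seg_mask(mask),
       label = lbl,
       lesion_area_px = sum(mask))
}

#' Generate a phantom dataset
#'
#' `n` phantoms with per-item seeds drawn from the master seed, plus a
#' manifest tibble recording every item's seed, label and lesion area.
#'
#' @param n number of phantoms (`>= 1`).
#' @param spec a [phantom_spec()].
#' @param seed master seed; item seeds are derived from it.
#' @return list with `slices`, `masks`, `labels` and `manifest`.
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = spec$seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  item_seeds <- sample.int(2147483646L, n)
  items <- lapply(item_seeds, function(s) generate_phantom(spec, seed = s))
  list(slices = lapply(items, `[[`, "slice"),
       masks = lapply(items, `[[`, "mask"),
       labels = vapply(items, `[[`, integer(1), "label"),
       manifest = tibble(
         id = sprintf("phantom-%04d", seq_len(n)),
         seed = item_seeds,
         label = vapply(items, `[[`, integer(1), "label"),
         lesion_area_px = vapply(items, function(x)
           as.integer(x$lesion_area_px), integer(1))))
}

#' Export a phantom dataset as NIfTI pairs
#'
#' Writes each phantom as a single-slice NIfTI image/mask pair readable
#' by [load_nifti_volume()], plus a CSV manifest, closing the loop for
#' end-to-end tests on disk.
#'
#' @param ds a dataset from [generate_dataset()].
#' @param dir writable output directory (created if missing).
#' @return the manifest file path, invisibly.
#' @export
export_phantom_nifti <- function(ds, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory: %s", dir), call. = FALSE)
  }
  if (file.access(dir, 2) != 0) {
    stop(sprintf("directory not writable: %s", dir), call. = FALSE)
  }
  n <- length(ds$slices)
  img_paths <- file.path(dir, sprintf("%s_flair.nii.gz", ds$manifest$id))
  msk_paths <- file.path(dir, sprintf("%s_seg.nii.gz", ds$manifest$id))
  for (i in seq_len(n)) {
    px <- pixels_of(ds$slices[[i]])
    write_nifti_volume(array(px, c(dim(px), 1L)), img_paths[i])
    mk <- as_binary_matrix(pixels_of(ds$masks[[i]]))
    write_nifti_volume(array(as.numeric(mk), c(dim(mk), 1L)), msk_paths[i])
  }
  manifest <- ds$manifest
  manifest$image <- basename(img_paths)
  manifest$mask <- basename(msk_paths)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
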