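#' Z-score normalize a slice
#'
#' Subtracts the slice mean and divides by the population standard
#' deviation, so the output has mean 0 and standard deviation 1.  This is
#' the network-input normalization and is applied after any augmentation
#' (noise and blur change the moments).
#'
#' @param s a [slice2d()] or matrix with at least two distinct values.
#' @return same container type as `s`.
#' @export
zscore_normalize <- function(s) {
  px <- pixels_of(s)
  mu <- mean(px)
  sigma <- sqrt(mean((px - mu)^2))
  if (sigma <= 0) {
    stop("cannot z-score a constant image (sd = 0)", call. = FALSE)
  }
  rewrap(s, (px - mu) / sigma)
}

#' Geometric augmentation primitives
#'
#' `flip_h()` reverses columns, `flip_v()` reverses rows, `rotate90()`
#' performs an exact quarter turn (`+90` = counter-clockwise), and
#' `shift_slice()` translates by whole pixels with zero fill (the
#' background of brain MRI is zero).  None of these interpolate.
#'
#' @param s a [slice2d()] or matrix.
#' @return same container type as `s`.
#' @export
flip_h <- function(s) {
  px <- pixels_of(s)
  rewrap(s, px[, rev(seq_len(ncol(px))), drop = FALSE])
}

#' @rdname flip_h
#' @export
flip_v <- function(s) {
  px <- pixels_of(s)
  rewrap(s, px[rev(seq_len(nrow(px))), , drop = FALSE])
}

#' @rdname flip_h
#' @param direction `+90` (counter-clockwise) or `-90` (clockwise).
#' @export
rotate90 <- function(s, direction = 90) {
  if (!direction %in% c(90, -90)) {
    stop("direction must be +90 or -90", call. = FALSE)
  }
  px <- pixels_of(s)
  out <- if (direction == 90) {
    t(px)[rev(seq_len(ncol(px))), , drop = FALSE]
  } else {
    t(px)[, rev(seq_len(nrow(px))), drop = FALSE]
  }
  rewrap(s, out)
}

#' @rdname flip_h
#' @param dx,dy integer shift in columns (`dx`) and rows (`dy`); a bright
#'   pixel at (r, c) moves to (r + dy, c + dx).
#' @export
shift_slice <- function(s, dx = 0L, dy = 0L) {
  px <- pixels_of(s)
  H <- nrow(px); W <- ncol(px)
  if (abs(dx) >= W || abs(dy) >= H) {
    stop("shift must be smaller than the image side", call. = FALSE)
  }
  out <- matrix(0, H, W)
  src_r <- seq_len(H) - dy
  src_c <- seq_len(W) - dx
  ok_r <- src_r >= 1 & src_r <= H
  ok_c <- src_c >= 1 & src_c <= W
  out[which(ok_r), which(ok_c)] <- px[src_r[ok_r], src_c[ok_c], drop = FALSE]
  rewrap(s, out)
}

#' Additive Gaussian noise
#'
#' Adds zero-mean Gaussian noise with standard deviation
#' `sigma * (max - min)` of the slice, so `sigma` is a fraction of the
#' intensity range.  Uses the session RNG unless `seed` is given.
#'
#' @param s a [slice2d()] or matrix.
#' @param sigma non-negative noise level as a fraction of the range.
#' @param seed optional integer for a reproducible draw.
#' @return same container type as `s`.
#' @export
add_noise <- function(s, sigma = 0.05, seed = NULL) {
  stopifnot(sigma >= 0)
  px <- pixels_of(s)
  if (sigma == 0) return(s)
  rng <- diff(range(px))
  if (rng == 0) return(s)
  if (!is.null(seed)) set.seed(seed)
  rewrap(s, px + matrix(rnorm(length(px), 0, sigma * rng), nrow(px)))
}

# separable Gaussian kernel, radius 3*sigma, normalized to sum 1
gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along rows of a matrix with reflective (symmetric)
# boundary, vectorized over columns
conv_rows_reflect <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  idx <- c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * mp[(i - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

#' Gaussian blur
#'
#' Separable Gaussian convolution with reflective boundary handling; the
#' kernel is normalized, so total intensity of interior-supported content
#' is preserved.  `sigma = 0` is the identity.
#'
#' @param s a [slice2d()] or matrix.
#' @param sigma blur standard deviation in pixels.
#' @return same container type as `s`.
#' @export
gaussian_blur <- function(s, sigma = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(s)
  px <- pixels_of(s)
  k <- gauss_kernel1d(sigma)
  out <- conv_rows_reflect(px, k)
  out <- t(conv_rows_reflect(t(out), k))
  rewrap(s, out)
}

#' Augmentation configuration
#'
#' The augmentation suite: horizontal/vertical flips (applied with the
#' given probabilities in sampling mode), exact +/-90 degree rotation,
#' whole-pixel shift, additive Gaussian noise, and Gaussian blur.  The
#' noise level defaults to 0.05 of the intensity range and the blur to
#' 1 px: visible but label-preserving perturbations.
#'
#' @param p_flip_h,p_flip_v flip probabilities in `[0, 1]`.
#' @param rotation_deg rotation magnitude; 90 enables the +/-90 turns,
#'   0 disables rotation.
#' @param shift_px shift magnitude in pixels (both axes).
#' @param noise_sigma noise level as a fraction of the intensity range.
#' @param blur_sigma blur standard deviation in pixels.
#' @param seed mandatory integer seed; the whole augmented dataset is a
#'   pure function of the inputs and this seed.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(p_flip_h = 0.5, p_flip_v = 0.5,
                           rotation_deg = 90, shift_px = 20L,
                           noise_sigma = 0.05, blur_sigma = 1,
                           seed = 1L) {
  stopifnot(p_flip_h >= 0, p_flip_h <= 1, p_flip_v >= 0, p_flip_v <= 1,
            shift_px >= 0, noise_sigma >= 0, blur_sigma >= 0,
            rotation_deg %in% c(0, 90))
  structure(list(p_flip_h = p_flip_h, p_flip_v = p_flip_v,
                 rotation_deg = rotation_deg, shift_px = as.integer(shift_px),
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "augment_config")
}

# names of the transforms enabled by a config; in "all" mode both
# rotation directions count separately, in sampling mode rotation is one
# family whose direction is drawn at random
enabled_transforms <- function(cfg, mode = "all") {
  out <- character()
  if (cfg$p_flip_h > 0) out <- c(out, "flip_h")
  if (cfg$p_flip_v > 0) out <- c(out, "flip_v")
  if (cfg$rotation_deg == 90) {
    out <- c(out, if (mode == "all") c("rot_p90", "rot_m90") else "rot")
  }
  if (cfg$shift_px > 0) out <- c(out, "shift")
  if (cfg$noise_sigma > 0) out <- c(out, "noise")
  if (cfg$blur_sigma > 0) out <- c(out, "blur")
  out
}

apply_transform <- function(px, name, cfg, mask = NULL) {
  geom <- function(f, ...) {
    list(pixels = f(px, ...),
         mask = if (is.null(mask)) NULL else as_binary_matrix(f(mask, ...)))
  }
  switch(name,
    flip_h  = geom(flip_h),
    flip_v  = geom(flip_v),
    rot     = geom(rotate90, direction = sample(c(90, -90), 1)),
    rot_p90 = geom(rotate90, direction = 90),
    rot_m90 = geom(rotate90, direction = -90),
    shift   = {
      sgn <- sample(c(-1L, 1L), 2, replace = TRUE)
      geom(shift_slice, dx = sgn[1] * cfg$shift_px, dy = sgn[2] * cfg$shift_px)
    },
    noise   = list(pixels = pixels_of(add_noise(px, cfg$noise_sigma)),
                   mask = mask),
    blur    = list(pixels = pixels_of(gaussian_blur(px, cfg$blur_sigma)),
                   mask = mask),
    stop("unknown transform: ", name)
  )
}

#' Build an augmented dataset
#'
#' Emits the original slices plus transformed copies, each keeping its
#' source label.  In `mode = "sample"` (default) the flips are included
#' with their configured probabilities and every other enabled transform
#' family with probability 1/2 (rotation picks +90 or -90 at random), so
#' the output is on average about 4x the input and reproducible from
#' `cfg$seed`.  In `mode = "all"` every enabled transform contributes
#' exactly one copy per input (both rotation directions), giving
#' `n * (1 + n_transforms)` items.
#' Ground-truth masks, when supplied, ride along: geometric transforms are
#' applied identically to the mask; noise and blur leave it untouched.
#'
#' @param slices list of [slice2d()]s or matrices.
#' @param labels one label per slice.
#' @param cfg an [augment_config()].
#' @param masks optional list of binary masks paired with `slices`.
#' @param mode `"sample"` or `"all"`.
#' @return list with `slices`, `labels`, `masks` (or NULL), `source` and
#'   `transform` bookkeeping vectors.
#' @export
build_augmented_dataset <- function(slices, labels, cfg = augment_config(),
                                    masks = NULL,
                                    mode = c("sample", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "augment_config"))
  if (length(slices) != length(labels)) {
    stop("one label per slice required", call. = FALSE)
  }
  if (!is.null(masks) && length(masks) != length(slices)) {
    stop("one mask per slice required", call. = FALSE)
  }
  set.seed(cfg$seed)
  tr_names <- enabled_transforms(cfg, mode)
  out_s <- list(); out_l <- c(); out_m <- list(); src <- c(); trf <- c()
  for (i in seq_along(slices)) {
    px <- pixels_of(slices[[i]])
    mk <- if (is.null(masks)) NULL else as_binary_matrix(pixels_of(masks[[i]]))
    out_s[[length(out_s) + 1L]] <- px
    out_m[[length(out_m) + 1L]] <- mk %||% NA
    out_l <- c(out_l, labels[i]); src <- c(src, i); trf <- c(trf, "original")
    for (nm in tr_names) {
      keep <- if (mode == "all") TRUE else {
        p <- switch(nm, flip_h = cfg$p_flip_h, flip_v = cfg$p_flip_v, 0.5)
        runif(1) < p
      }
      if (!keep) next
      tx <- apply_transform(px, nm, cfg, mask = mk)
      out_s[[length(out_s) + 1L]] <- tx$pixels
      out_m[[length(out_m) + 1L]] <- tx$mask %||% NA
      out_l <- c(out_l, labels[i]); src <- c(src, i); trf <- c(trf, nm)
    }
  }
  list(slices = out_s, labels = out_l,
       masks = if (is.null(masks)) NULL else out_m,
       source = src, transform = trf)
}
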