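#' Spatial gradient of a 2D map
#'
#' Forward differences with unit step: `H[i, j] = X[i, j+1] - X[i, j]`
#' (horizontal) and `V[i, j] = X[i+1, j] - X[i, j]` (vertical).  The
#' trailing column of `H` and trailing row of `V`, where the difference
#' is undefined, are set to 0 — a neutral value for the mean/max pooling
#' of magnitudes downstream.
#'
#' @param map numeric matrix, at least 2 x 2.
#' @return list with matrices `H` and `V` of the same shape as `map`.
#' @export
spatial_gradient <- function(map) {
  map <- pixels_of(map)
  if (nrow(map) < 2 || ncol(map) < 2) {
    stop("map must be at least 2 x 2", call. = FALSE)
  }
  H <- matrix(0, nrow(map), ncol(map))
  V <- matrix(0, nrow(map), ncol(map))
  H[, -ncol(map)] <- map[, -1, drop = FALSE] - map[, -ncol(map), drop = FALSE]
  V[-nrow(map), ] <- map[-1, , drop = FALSE] - map[-nrow(map), , drop = FALSE]
  list(H = H, V = V)
}

#' Gradient magnitude
#'
#' Scalarizes the per-pixel gradient 2-vector `[H, V]` as its Euclidean
#' norm `sqrt(H^2 + V^2)`.
#'
#' @param H,V difference grids of identical shape.
#' @return non-negative matrix of the same shape.
#' @export
gradient_magnitude <- function(H, V) {
  if (!all(dim(H) == dim(V))) {
    stop("H and V must have the same shape", call. = FALSE)
  }
  sqrt(H^2 + V^2)
}

#' Per-map gradient stack
#'
#' Applies [spatial_gradient()] and [gradient_magnitude()] to every map
#' of a feature stack.
#'
#' @param f a [feature_stack()] or 3D array.
#' @return an object of class `gradient_stack`: list with 3D arrays `H`,
#'   `V` and `magnitude`.
#' @export
gradient_stack <- function(f) {
  stopifnot(length(dim(f)) == 3)
  H <- array(0, dim(f)); V <- array(0, dim(f)); M <- array(0, dim(f))
  for (k in seq_len(dim(f)[3])) {
    g <- spatial_gradient(f[, , k])
    H[, , k] <- g$H; V[, , k] <- g$V
    M[, , k] <- gradient_magnitude(g$H, g$V)
  }
  structure(list(H = H, V = V, magnitude = M), class = "gradient_stack")
}

#' Pool gradient magnitudes into per-map weights
#'
#' Condenses each map's gradient-magnitude grid into two scalars — its
#' average and its global maximum — giving two weight vectors of length
#' equal to the number of maps (32 for the full-width network) instead of
#' a full `(K, N, N)` tensor.
#'
#' @param g a `gradient_stack` (or a [feature_stack()], which is
#'   converted first).
#' @return an object of class `pooled_weights`: list with `mean_vec` and
#'   `max_vec`.
#' @export
pool_gradient_weights <- function(g) {
  if (!inherits(g, "gradient_stack")) g <- gradient_stack(g)
  M <- g$magnitude
  if (dim(M)[3] < 1) stop("empty stack", call. = FALSE)
  structure(list(
    mean_vec = apply(M, 3, mean),
    max_vec = apply(M, 3, max)),
    class = "pooled_weights")
}

#' Weight feature maps by their pooled gradient statistics
#'
#' Multiplies each feature map component-wise by its scalar weights
#' (`component1 x filter1`, `component2 x filter2`, ...).  With
#' `combine = "product"` (default) the effective weight of map `k` is
#' `mean_vec[k] * max_vec[k]`, so both pooled vectors act and exactly one
#' weighted stack comes out.  `combine = "stack_mean"` instead averages
#' the mean-weighted and max-weighted stacks.
#'
#' @param f a [feature_stack()] or 3D array.
#' @param w a `pooled_weights` whose vectors match the map count.
#' @param combine `"product"` or `"stack_mean"`.
#' @return a [feature_stack()] with the same number of maps.
#' @export
weight_feature_maps <- function(f, w, combine = c("product", "stack_mean")) {
  combine <- match.arg(combine)
  stopifnot(inherits(w, "pooled_weights"), length(dim(f)) == 3)
  K <- dim(f)[3]
  if (length(w$mean_vec) != K || length(w$max_vec) != K) {
    stop("weight vector length must equal the map count", call. = FALSE)
  }
  wk <- switch(combine,
               product = w$mean_vec * w$max_vec,
               stack_mean = (w$mean_vec + w$max_vec) / 2)
  out <- array(0, dim(f))
  for (k in seq_len(K)) out[, , k] <- f[, , k] * wk[k]
  feature_stack(out)
}

#' Mean image of a stack
#'
#' Per-pixel arithmetic mean over the maps: the single candidate
#' saliency image.
#'
#' @param f a [feature_stack()] or 3D array.
#' @return numeric matrix.
#' @export
mean_saliency <- function(f) {
  stopifnot(length(dim(f)) == 3, dim(f)[3] >= 1)
  apply(f, c(1, 2), mean)
}

#' Normalize a map to grayscale
#'
#' Clamps negatives to zero and scales by the global maximum so the
#' result lies in `[0, 1]` with maximum exactly 1 whenever any positive
#' response exists.  An all-zero (or all-negative) input maps to all
#' zeros — no division takes place.
#'
#' @param m numeric matrix.
#' @return a [saliency_map()].
#' @export
normalize_to_grayscale <- function(m) {
  m <- pixels_of(m)
  if (any(!is.finite(m))) stop("non-finite values", call. = FALSE)
  m <- pmax(m, 0)
  mx <- max(m)
  if (mx > 0) m <- m / mx
  saliency_map(m)
}

#' Upsample a saliency map
#'
#' Bilinear upsampling to the slice geometry, so the 32 x 32 map can mask
#' and overlay the 128 x 128 input.  Values stay in `[0, 1]`.
#'
#' @param m a [saliency_map()] (or matrix in `[0, 1]`).
#' @param target_dim integer length-2 target shape (rows, cols), at least
#'   the source shape.
#' @return a [saliency_map()] of shape `target_dim`.
#' @export
upsample_saliency <- function(m, target_dim) {
  src <- dim(m)
  if (any(target_dim < src)) {
    stop("target shape must be >= source shape", call. = FALSE)
  }
  out <- resize_bilinear(unclass(m), target_dim[1], target_dim[2])
  saliency_map(clamp01(out), source_shape = src)
}

#' Jet-style colormap
#'
#' Deterministic piecewise-linear jet mapping from grayscale in `[0, 1]`
#' to three channels in `[0, 1]`.  Gray 0 maps to dark blue
#' `(0, 0, 0.5)` and gray 1 to dark red `(0.5, 0, 0)`.
#'
#' @param m a [saliency_map()] or matrix in `[0, 1]`.
#' @return `(N, N, 3)` array of RGB values in `[0, 1]`.
#' @export
apply_colormap <- function(m) {
  x <- unclass(pixels_of(m))
  if (min(x) < 0 || max(x) > 1) stop("input must lie in [0, 1]",
                                     call. = FALSE)
  jet <- function(v) clamp01(1.5 - abs(v))
  out <- array(0, c(dim(x), 3))
  out[, , 1] <- jet(4 * x - 3)
  out[, , 2] <- jet(4 * x - 2)
  out[, , 3] <- jet(4 * x - 1)
  out
}

#' Grayscale slice as RGB
#'
#' Min-max scales a slice to `[0, 1]` and replicates it over three
#' channels for display and overlay.
#'
#' @param s a [slice2d()] or matrix.
#' @return `(N, N, 3)` array.
#' @export
gray_to_rgb <- function(s) {
  px <- pixels_of(s)
  rng <- range(px)
  g <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  array(rep(g, 3), c(dim(g), 3))
}

#' Superimpose a colormapped saliency on a slice
#'
#' Pixel-wise `slice + alpha * colormap`, clipped to the display range
#' `[0, 1]`.
#'
#' @param base_rgb `(N, N, 3)` slice image in `[0, 1]`.
#' @param overlay_rgb `(N, N, 3)` colormapped saliency.
#' @param alpha overlay weight in `[0, 1]` (default 0.4).
#' @return `(N, N, 3)` array in `[0, 1]`.
#' @export
superimpose <- function(base_rgb, overlay_rgb, alpha = 0.4) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!all(dim(base_rgb) == dim(overlay_rgb))) {
    stop("shapes must match", call. = FALSE)
  }
  clamp01(base_rgb + alpha * overlay_rgb)
}

#' Threshold a saliency map
#'
#' @param m a [saliency_map()].
#' @param tau threshold in `[0, 1]`; pixels with gray `>= tau` are set.
#' @return a [seg_mask()] with `threshold_used = tau`.
#' @export
threshold_mask <- function(m, tau) {
  stopifnot(tau >= 0, tau <= 1)
  seg_mask((unclass(m) >= tau) * 1L, threshold_used = tau,
           provenance = "fixed")
}

#' Default threshold grid
#'
#' The evaluation sweep 0.33, 0.35, ..., 0.85 (step 0.02, 27 values).
#'
#' @return numeric vector of thresholds.
#' @export
default_taus <- function() seq(0.33, 0.85, by = 0.02)

#' Threshold sweep against a reference mask
#'
#' Applies every candidate threshold, optionally post-processes each
#' mask, scores the Dice similarity against the reference, and returns
#' the argmax threshold (ties broken toward the smallest tau).  When a
#' post-processing configuration is given, selection uses the
#' post-processed Dice and the table reports both raw and post-processed
#' scores per threshold.
#'
#' @param m a [saliency_map()] aligned with `ref`.
#' @param ref reference binary mask.
#' @param taus candidate thresholds (default [default_taus()]).
#' @param post optional [postprocess_config()] applied before scoring.
#' @return list with `best_tau`, `mask` (the selected, post-processed
#'   [seg_mask()]), `mask_raw`, `table` (tibble: tau, dsc_raw, dsc_post),
#'   and `empty_ref` flag.
#' @export
threshold_sweep <- function(m, ref, taus = default_taus(), post = NULL) {
  stopifnot(length(taus) >= 1)
  ref <- as_binary_matrix(pixels_of(ref))
  if (!all(dim(m) == dim(ref))) {
    stop("reference mask must align with the saliency map", call. = FALSE)
  }
  taus <- sort(taus)
  dsc_raw <- numeric(length(taus))
  dsc_post <- rep(NA_real_, length(taus))
  masks_raw <- vector("list", length(taus))
  masks_post <- vector("list", length(taus))
  for (i in seq_along(taus)) {
    mk <- threshold_mask(m, taus[i])
    masks_raw[[i]] <- mk
    dsc_raw[i] <- as.numeric(dice(ref, mk))
    if (!is.null(post)) {
      mp <- postprocess_mask(mk, post)
      masks_post[[i]] <- mp
      dsc_post[i] <- as.numeric(dice(ref, mp))
    }
  }
  score <- if (is.null(post)) dsc_raw else dsc_post
  best <- which.max(score)            # first max: smallest tau on ties
  best_mask <- if (is.null(post)) masks_raw[[best]] else masks_post[[best]]
  attr(best_mask, "provenance") <- "sweep"
  attr(best_mask, "threshold_used") <- taus[best]
  list(best_tau = taus[best],
       mask = best_mask,
       mask_raw = masks_raw[[best]],
       table = tibble(tau = taus, dsc_raw = dsc_raw, dsc_post = dsc_post),
       empty_ref = sum(ref) == 0)
}

#' Segment a tumor slice from its feature-map gradients
#'
#' The full mask-free segmentation pipeline: classify the slice; if the
#' tumor class wins, take the last-convolution feature maps, compute
#' their spatial gradients and magnitudes, pool each map's mean and
#' maximum magnitude into weight vectors, re-weight the maps, average
#' them into one image, normalize to grayscale, upsample to the slice
#' geometry, threshold (fixed tau, or a sweep against a reference mask),
#' post-process, and build the colormap overlay.
#'
#' @param net a trained `tumor_cnn`.
#' @param s a normalized `input_side x input_side` [slice2d()] or matrix.
#' @param mode `"fixed"` (deployment: threshold `tau`, no reference
#'   needed) or `"sweep"` (evaluation: pick the Dice-optimal threshold
#'   against `ref`).
#' @param ref reference binary mask, required for `mode = "sweep"`.
#' @param tau fixed threshold (default 0.5), used when `mode = "fixed"`.
#' @param post a [postprocess_config()]; `NULL` disables post-processing.
#' @param alpha overlay weight for [superimpose()].
#' @param combine pooled-weight combination rule, see
#'   [weight_feature_maps()].
#' @param display_slice optional unnormalized slice used for the overlay
#'   background (defaults to `s`).
#' @return an object of class `seg_result`: list with `tumor_detected`,
#'   `label`, `score`, and — when a tumor is detected — `mask`,
#'   `mask_raw`, `saliency` (upsampled), `overlay`, `tau`, `sweep`
#'   (tibble or NULL).  When the classifier votes not-tumor the result
#'   carries `tumor_detected = FALSE` and no mask.
#' @export
segment_slice <- function(net, s, mode = c("sweep", "fixed"), ref = NULL,
                          tau = 0.5, post = postprocess_config(),
                          alpha = 0.4,
                          combine = c("product", "stack_mean"),
                          display_slice = NULL) {
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  if (mode == "sweep" && is.null(ref)) {
    stop("sweep mode requires a reference mask", call. = FALSE)
  }
  cls <- classify_slice(net, s)
  if (cls$class != 1L) {
    return(structure(list(tumor_detected = FALSE, label = cls$label,
                          score = cls$score), class = "seg_result"))
  }
  w <- pool_gradient_weights(gradient_stack(cls$features))
  weighted <- weight_feature_maps(cls$features, w, combine = combine)
  sal <- normalize_to_grayscale(mean_saliency(weighted))
  sal_up <- upsample_saliency(sal, dim(pixels_of(s)))

  if (mode == "sweep") {
    sw <- threshold_sweep(sal_up, ref, post = post)
    mask <- sw$mask
    mask_raw <- sw$mask_raw
    tau_used <- sw$best_tau
    sweep_tbl <- sw$table
  } else {
    mask_raw <- threshold_mask(sal_up, tau)
    mask <- if (is.null(post)) mask_raw else postprocess_mask(mask_raw, post)
    tau_used <- tau
    sweep_tbl <- NULL
  }
  base <- gray_to_rgb(display_slice %||% s)
  overlay <- superimpose(base, apply_colormap(sal_up), alpha = alpha)
  structure(list(tumor_detected = TRUE, label = cls$label,
                 score = cls$score, mask = mask, mask_raw = mask_raw,
                 saliency = sal_up, overlay = overlay, tau = tau_used,
                 sweep = sweep_tbl),
            class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  if (!x$tumor_detected) {
    cat(sprintf("<seg_result> no tumor detected (score %.3f)\n", x$score))
  } else {
    cat(sprintf(
      "<seg_result> tumor (score %.3f), tau %.2f, mask %d px\n",
      x$score, x$tau, sum(x$mask)))
  }
  invisible(x)
}
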