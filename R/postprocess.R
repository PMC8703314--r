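#' Post-processing configuration
#'
#' @param corner_margin width in pixels of the border band; connected
#'   components confined to the band are treated as scan-corner
#'   artifacts and removed (default 10).
#' @param opening_kernel odd side of the square structuring element for
#'   morphological opening (default 3).
#' @param min_component_px optional minimum component size kept after
#'   opening and border removal (0 disables the filter).
#' @return an object of class `postprocess_config`.
#' @export
postprocess_config <- function(corner_margin = 10L, opening_kernel = 3L,
                               min_component_px = 0L) {
  stopifnot(corner_margin >= 0, opening_kernel >= 1,
            opening_kernel %% 2 == 1, min_component_px >= 0)
  structure(list(corner_margin = as.integer(corner_margin),
                 opening_kernel = as.integer(opening_kernel),
                 min_component_px = as.integer(min_component_px)),
            class = "postprocess_config")
}

# carry seg_mask attributes from `src` onto binary matrix `m`
keep_mask_attrs <- function(m, src) {
  if (inherits(src, "seg_mask")) {
    seg_mask(m, threshold_used = attr(src, "threshold_used"),
             provenance = attr(src, "provenance") %||% "fixed")
  } else {
    m
  }
}

#' Morphological opening
#'
#' Erosion followed by dilation with a square structuring element of
#' ones.  Anti-extensive (result is a subset of the input), monotone and
#' idempotent; components too small to contain the element vanish.
#'
#' @param mask binary matrix or [seg_mask()].
#' @param kernel odd structuring-element side (default 3).
#' @return mask of the same type, opened.
#' @export
morphological_opening <- function(mask, kernel = 3L) {
  stopifnot(kernel >= 1, kernel %% 2 == 1)
  m <- as_binary_matrix(pixels_of(mask))
  if (kernel == 1L || sum(m) == 0) return(keep_mask_attrs(m, mask))
  brush <- EBImage::makeBrush(kernel, shape = "box")
  out <- EBImage::opening(EBImage::Image(m), brush)
  keep_mask_attrs(as_binary_matrix(EBImage::imageData(out)), mask)
}

#' Remove components confined to the image border
#'
#' Labels the mask's 8-connected components and deletes every component
#' whose pixels all lie within `margin` pixels of the image border (the
#' corner/edge artifact band); a component with any interior pixel
#' survives intact.
#'
#' @param mask binary matrix or [seg_mask()].
#' @param margin band width in pixels; 0 removes nothing.
#' @return mask of the same type.
#' @export
remove_border_components <- function(mask, margin = 10L) {
  stopifnot(margin >= 0)
  m <- as_binary_matrix(pixels_of(mask))
  if (margin == 0L || sum(m) == 0) return(keep_mask_attrs(m, mask))
  lab <- label_components_cpp(m)
  H <- nrow(m); W <- ncol(m)
  dist_border <- pmin(row(m) - 1L, H - row(m), col(m) - 1L, W - col(m))
  interior <- dist_border >= margin
  keep <- sort(unique(lab[lab > 0 & interior]))
  out <- matrix(as.integer(lab > 0 & lab %in% keep), H, W)
  keep_mask_attrs(out, mask)
}

# drop 8-connected components below a pixel-count floor
filter_small_components <- function(mask, min_px) {
  m <- as_binary_matrix(pixels_of(mask))
  if (min_px <= 1L || sum(m) == 0) return(keep_mask_attrs(m, mask))
  lab <- label_components_cpp(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  out <- matrix(as.integer(lab > 0 & lab %in% keep), nrow(m), ncol(m))
  keep_mask_attrs(out, mask)
}

#' Clean a raw thresholded mask
#'
#' Morphological opening, then removal of border-confined components,
#' then the optional minimum-size filter.  Opening runs first so that a
#' thin bridge between a border artifact and true tumor is cut before
#' component removal decides what is border-confined.  The pixel count
#' never increases, and applying the pipeline twice equals applying it
#' once.
#'
#' @param mask binary matrix or [seg_mask()].
#' @param cfg a [postprocess_config()].
#' @return cleaned mask of the same type.
#' @export
postprocess_mask <- function(mask, cfg = postprocess_config()) {
  stopifnot(inherits(cfg, "postprocess_config"))
  out <- morphological_opening(mask, cfg$opening_kernel)
  out <- remove_border_components(out, cfg$corner_margin)
  out <- filter_small_components(out, cfg$min_component_px)
  out
}
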