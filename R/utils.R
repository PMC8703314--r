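`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Extract the pixel matrix from a slice2d or pass a bare matrix through.
pixels_of <- function(s) {
  if (inherits(s, "slice2d")) s$pixels else s
}

# Return `px` in the same container as `s` (slice2d metadata preserved).
rewrap <- function(s, px) {
  if (inherits(s, "slice2d")) {
    s$pixels <- px
    s
  } else {
    px
  }
}

#' Derive a per-stage seed from the global seed
#'
#' One global seed drives every random stage of a run (phantom generation,
#' weight initialization, train/validation split, shuffling).  Each stage
#' gets its own stream by hashing the stage name into the seed, so adding
#' a stage never perturbs the draws of another.  The result always lies in
#' `[0, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param stage character stage name, e.g. `"phantoms"`, `"train"`.
#' @return integer seed for [set.seed()].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1999993
  as.integer((abs(seed) %% 1000003 + h * 1009 + 17) %% 2147483646)
}

# Bilinear resize via EBImage, with an exact identity shortcut so that a
# no-op resize is bit-identical.
resize_bilinear <- function(m, rows, cols) {
  if (nrow(m) == rows && ncol(m) == cols) {
    return(m)
  }
  out <- EBImage::resize(EBImage::Image(m), w = rows, h = cols,
                         filter = "bilinear")
  EBImage::imageData(out)
}
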