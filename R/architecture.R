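BASE_FILTERS <- c(512L, 256L, 128L, 64L, 32L)

#' The 18-layer classifier architecture
#'
#' Returns the fixed layer stack of the tumor/not-tumor classifier: five
#' 3x3 stride-1 SAME convolutions with filter counts 512, 256, 128, 64
#' and 32 (each followed by a ReLU activation layer), 2x2 stride-2 max
#' pooling after the activations of layers 2, 7 and 12, a flatten, a
#' 32-unit fully connected layer with ReLU, and a 2-unit output layer
#' with softmax.  A `scale` divisor shrinks all filter counts uniformly
#' for desk-scale training; the spatial arithmetic is unchanged.
#'
#' @param scale integer divisor of the filter counts, one of 1, 2, 4, 8.
#' @return an object of class `architecture_spec`: a list of layer
#'   descriptors plus the scaled filter counts.
#' @export
architecture_spec <- function(scale = 1L) {
  if (!scale %in% c(1L, 2L, 4L, 8L)) {
    stop("scale must be one of 1, 2, 4, 8", call. = FALSE)
  }
  f <- BASE_FILTERS %/% as.integer(scale)
  layers <- list(
    list(type = "conv", filters = f[1], kernel = 3L, stride = 1L),
    list(type = "activation", fun = "relu"),
    list(type = "maxpool", window = 2L, stride = 2L),
    list(type = "conv", filters = f[2], kernel = 3L, stride = 1L),
    list(type = "activation", fun = "relu"),
    list(type = "conv", filters = f[3], kernel = 3L, stride = 1L),
    list(type = "activation", fun = "relu"),
    list(type = "maxpool", window = 2L, stride = 2L),
    list(type = "conv", filters = f[4], kernel = 3L, stride = 1L),
    list(type = "activation", fun = "relu"),
    list(type = "conv", filters = f[5], kernel = 3L, stride = 1L),
    list(type = "activation", fun = "relu"),
    list(type = "maxpool", window = 2L, stride = 2L),
    list(type = "flatten"),
    list(type = "fc", units = 32L),
    list(type = "activation", fun = "relu"),
    list(type = "fc", units = 2L),
    list(type = "activation", fun = "softmax")
  )
  structure(list(layers = layers, filters = f, scale = as.integer(scale)),
            class = "architecture_spec")
}

#' Propagate shapes through the architecture
#'
#' Symbolically pushes an `input_side x input_side` single-channel input
#' through the layer stack and reports every layer's output shape.  At
#' `scale = 1` with a 128 x 128 input this reproduces the published
#' per-layer output column (512 x 128 x 128 down to 32 x 16 x 16, then
#' 8192, 32, 2).
#'
#' @param spec an [architecture_spec()].
#' @param input_side input side length (must be divisible by 8).
#' @return a tibble with one row per layer: `layer`, `type`, `channels`,
#'   `height`, `width`, `units`.
#' @export
architecture_shapes <- function(spec = architecture_spec(),
                                input_side = 128L) {
  stopifnot(inherits(spec, "architecture_spec"), input_side %% 8 == 0)
  ch <- 1L; h <- input_side; w <- input_side; units <- NA_integer_
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type == "conv") {
      ch <- ly$filters                       # stride 1, SAME: spatial kept
    } else if (ly$type == "maxpool") {
      h <- h %/% ly$stride; w <- w %/% ly$stride
    } else if (ly$type == "flatten") {
      units <- ch * h * w
      ch <- NA_integer_; h <- NA_integer_; w <- NA_integer_
    } else if (ly$type == "fc") {
      units <- ly$units
    }                                        # activations keep the shape
    rows[[i]] <- tibble(layer = i, type = ly$type, channels = ch,
                        height = h, width = w, units = units)
  }
  dplyr::bind_rows(rows)
}

#' Flatten width of the architecture
#'
#' @param spec an [architecture_spec()].
#' @param input_side input side length.
#' @return integer number of flattened features (8192 at scale 1 with a
#'   128 x 128 input).
#' @export
flatten_width <- function(spec = architecture_spec(), input_side = 128L) {
  sh <- architecture_shapes(spec, input_side)
  sh$units[sh$type == "flatten"]
}

# Glorot-uniform limit for a 3x3 conv or a dense layer
glorot_limit <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

#' Build a trainable network
#'
#' Realizes the [architecture_spec()] with seeded Glorot-uniform kernel
#' initialization and zero biases.  Weights for convolution `l` are stored
#' as a `filters x (9 * in_channels)` matrix matching the im2col layout of
#' the compiled engine.
#'
#' @param scale filter-count divisor (1, 2, 4 or 8); `scale > 1` gives the
#'   desk-scale variant with identical shape ratios.
#' @param seed integer seed for the weight draw.
#' @param input_side network input side (default 128).
#' @return an object of class `tumor_cnn`.
#' @export
build_network <- function(scale = 1L, seed = 1L, input_side = 128L) {
  spec <- architecture_spec(scale)
  f <- spec$filters
  fan_chain <- c(1L, f)                      # input channels per conv layer
  set.seed(seed)
  params <- list()
  for (l in 1:5) {
    cin <- fan_chain[l]; cout <- fan_chain[l + 1]
    lim <- glorot_limit(9 * cin, 9 * cout)
    params[[2 * l - 1]] <- matrix(runif(cout * 9 * cin, -lim, lim),
                                  cout, 9 * cin)
    params[[2 * l]] <- numeric(cout)
  }
  nflat <- flatten_width(spec, input_side)
  lim <- glorot_limit(nflat, 32)
  params[[11]] <- matrix(runif(32 * nflat, -lim, lim), 32, nflat)
  params[[12]] <- numeric(32)
  lim <- glorot_limit(32, 2)
  params[[13]] <- matrix(runif(2 * 32, -lim, lim), 2, 32)
  params[[14]] <- numeric(2)
  names(params) <- paste0(rep(c("W", "b"), 7), rep(1:7, each = 2))
  structure(list(spec = spec, scale = spec$scale,
                 input_side = as.integer(input_side),
                 params = params, seed = as.integer(seed),
                 history = NULL, trained = FALSE),
            class = "tumor_cnn")
}

#' @export
print.tumor_cnn <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "<tumor_cnn> 18-layer binary classifier, scale %d (filters %s)\n",
    x$scale, paste(x$spec$filters, collapse = "/")))
  cat(sprintf("  input %d x %d, %s parameters, %s\n", x$input_side,
              x$input_side, format(np, big.mark = ","),
              if (x$trained) sprintf("trained %d epoch(s)", nrow(x$history))
              else "untrained"))
  invisible(x)
}
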