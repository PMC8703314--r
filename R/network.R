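#' Binary cross-entropy loss
#'
#' The averaged binary cross-entropy over all scalar outputs:
#' `-(1/n) * sum(y * log(yhat) + (1 - y) * log(1 - yhat))`, with
#' predictions clipped to `[eps, 1 - eps]` before the logarithms.
#'
#' @param y targets (one-hot vectors/matrices of 0s and 1s).
#' @param yhat predicted scores of the same shape, in `[0, 1]`.
#' @param eps clipping constant, default `1e-7`.
#' @return non-negative scalar loss.
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  if (length(y) != length(yhat)) {
    stop("y and yhat must have the same shape", call. = FALSE)
  }
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Polynomial learning-rate decay
#'
#' `alpha = alpha0 * (1 - e / Ne)^0.9`: the Adam step size starts at
#' `alpha0` for epoch counter `e = 0`, decreases strictly, and reaches 0
#' at `e = Ne`.
#'
#' @param e epoch counter, `0 <= e <= Ne`.
#' @param Ne total number of epochs.
#' @param alpha0 initial learning rate (default `1e-4`).
#' @return the learning rate for epoch `e`.
#' @export
lr_schedule <- function(e, Ne, alpha0 = 1e-4) {
  if (any(e < 0) || any(e > Ne)) {
    stop("epoch counter must satisfy 0 <= e <= Ne", call. = FALSE)
  }
  alpha0 * (1 - e / Ne)^0.9
}

#' Derive slice labels from ground-truth masks
#'
#' A slice is labeled tumor (1) when its mask has at least
#' `tumor_pixel_min` nonzero pixels, else not-tumor (0).
#'
#' @param masks list of binary masks (one per slice).
#' @param tumor_pixel_min minimum nonzero pixel count for a tumor label.
#' @return integer vector of 0/1 labels.
#' @export
derive_labels <- function(masks, tumor_pixel_min = 1L) {
  vapply(masks, function(m) {
    as.integer(sum(pixels_of(m) != 0) >= tumor_pixel_min)
  }, integer(1))
}

#' Training configuration
#'
#' @param epochs maximum number of epochs (published setting: 45).
#' @param batch_size minibatch size (published setting: 20).
#' @param alpha0 initial Adam learning rate (published setting: 1e-4).
#' @param split_ratio training fraction of the 70:30 random split.
#' @param seed integer seed covering the split and all shuffling.
#' @param tumor_pixel_min labeling rule passed to [derive_labels()].
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 45L, batch_size = 20L, alpha0 = 1e-4,
                         split_ratio = 0.70, seed = 1L,
                         tumor_pixel_min = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, split_ratio > 0, split_ratio < 1,
            alpha0 > 0, tumor_pixel_min >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 alpha0 = alpha0, split_ratio = split_ratio,
                 seed = as.integer(seed),
                 tumor_pixel_min = as.integer(tumor_pixel_min)),
            class = "train_config")
}

# slices (list of matrices or H x W x N array) -> H x W x N array
as_slice_cube <- function(slices, side) {
  if (is.array(slices) && length(dim(slices)) == 3) return(slices)
  stopifnot(is.list(slices))
  px <- lapply(slices, pixels_of)
  bad <- !vapply(px, function(m) all(dim(m) == side), logical(1))
  if (any(bad)) {
    stop(sprintf("all slices must be %d x %d (resize first)", side, side),
         call. = FALSE)
  }
  array(unlist(px, use.names = FALSE), dim = c(side, side, length(px)))
}

# seeded stratified split: returns list(train, val) of indices
stratified_split <- function(labels, split_ratio, seed) {
  set.seed(seed)
  train_idx <- integer()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_tr <- round(length(idx) * split_ratio)
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  list(train = train_idx,
       val = setdiff(seq_along(labels), train_idx))
}

#' Train the classifier
#'
#' Minibatch Adam on the clipped binary cross-entropy, with the
#' polynomial learning-rate decay of [lr_schedule()] applied per epoch
#' (epoch `k` uses `lr_schedule(k - 1, epochs)`, so the first epoch runs
#' at `alpha0`).  The data are split 70:30 into train and validation by a
#' seeded, label-stratified random permutation.  Given the seed and
#' single-threaded numerics, training is bit-reproducible.
#'
#' @param net an untrained or trained [build_network()] object.
#' @param slices list of normalized `input_side x input_side` matrices
#'   (or a 3D array).
#' @param labels integer 0/1 labels, 1 = tumor; both classes must occur.
#' @param config a [train_config()].
#' @param validation optional list with `slices` and `labels`: when
#'   given, all of `slices` are used for training and this set is used
#'   for the per-epoch validation metrics instead of an internal split.
#' @param verbose print one line per epoch.
#' @return the trained `tumor_cnn`, with `history` (tibble: epoch, lr,
#'   train_loss, train_acc, val_loss, val_acc) and the split indices in
#'   `split` (when the internal split was used).
#' @export
train_network <- function(net, slices, labels, config = train_config(),
                          validation = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "tumor_cnn"), inherits(config, "train_config"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("training needs both classes present", call. = FALSE)
  }
  xs <- as_slice_cube(slices, net$input_side)
  n <- dim(xs)[3]
  stopifnot(length(labels) == n)

  set.seed(config$seed)
  if (is.null(validation)) {
    sp <- stratified_split(labels, config$split_ratio, config$seed)
    x_tr <- xs[, , sp$train, drop = FALSE]
    y_tr <- labels[sp$train]
    x_va <- xs[, , sp$val, drop = FALSE]
    y_va <- labels[sp$val]
  } else {
    sp <- NULL
    x_tr <- xs
    y_tr <- labels
    x_va <- as_slice_cube(validation$slices, net$input_side)
    y_va <- as.integer(validation$labels)
  }

  params <- net$params
  m_t <- lapply(params, function(p) p * 0)
  v_t <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  hist_rows <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch - 1, config$epochs, config$alpha0)
    ord <- sample(length(y_tr))
    ep_loss <- 0; ep_correct <- 0L
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      res <- cnn_grad_batch_cpp(x_tr[, , bi, drop = FALSE], params,
                                as.integer(y_tr[bi]))
      if (!all(is.finite(res$losses))) {
        stop(sprintf("non-finite training loss at epoch %d", epoch),
             call. = FALSE)
      }
      ep_loss <- ep_loss + sum(res$losses)
      ep_correct <- ep_correct +
        sum((res$probs[, 2] > res$probs[, 1]) == (y_tr[bi] == 1L))
      step <- step + 1L
      nb <- length(bi)
      for (l in seq_along(params)) {
        g <- res$grads[[l]] / nb
        m_t[[l]] <- beta1 * m_t[[l]] + (1 - beta1) * g
        v_t[[l]] <- beta2 * v_t[[l]] + (1 - beta2) * g^2
        mhat <- m_t[[l]] / (1 - beta1^step)
        vhat <- v_t[[l]] / (1 - beta2^step)
        params[[l]] <- params[[l]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    va <- eval_set(params, x_va, y_va)
    hist_rows[[epoch]] <- tibble(
      epoch = epoch, lr = lr,
      train_loss = ep_loss / length(y_tr),
      train_acc = ep_correct / length(y_tr),
      val_loss = va$loss, val_acc = va$acc)
    if (verbose) {
      message(sprintf(
        "epoch %2d  lr %.3g  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
        epoch, lr, ep_loss / length(y_tr), ep_correct / length(y_tr),
        va$loss, va$acc))
    }
  }

  net$params <- params
  net$history <- dplyr::bind_rows(hist_rows)
  net$trained <- TRUE
  net$split <- sp
  net$train_config <- config
  net
}

# mean clipped BCE and accuracy of a parameter set on a labeled cube
eval_set <- function(params, xs, y) {
  if (length(y) == 0) return(list(loss = NA_real_, acc = NA_real_))
  probs <- cnn_forward_batch_cpp(xs, params)
  onehot <- cbind(1 - y, y)
  list(loss = bce_loss(onehot, probs),
       acc = mean((probs[, 2] > probs[, 1]) == (y == 1L)))
}

#' Classify a slice and expose the last-layer feature maps
#'
#' Runs the forward pass on an already resized and normalized slice.
#' Besides the class decision, returns the post-ReLU feature maps of the
#' last convolution layer (before the final pooling, i.e. 32 x 32 at
#' scale 1), which feed the gradient-saliency segmentation stage.  Set
#' `pooled = TRUE` to get the post-pooling 16 x 16 maps instead.
#'
#' @param net a `tumor_cnn`.
#' @param s a [slice2d()] or matrix of side `net$input_side`.
#' @param pooled return the feature maps after the final max pooling.
#' @return list with `label` (`"tumor"`/`"not_tumor"`), `class` (0/1),
#'   `score` (probability of the decided class), `probs` (length 2),
#'   and `features` (a [feature_stack()]).
#' @export
classify_slice <- function(net, s, pooled = FALSE) {
  stopifnot(inherits(net, "tumor_cnn"))
  px <- pixels_of(s)
  if (!all(dim(px) == net$input_side)) {
    stop(sprintf("input must be %d x %d", net$input_side, net$input_side),
         call. = FALSE)
  }
  out <- cnn_forward_cpp(px, net$params, want_features = TRUE)
  feats <- out$features
  if (pooled) {
    side <- dim(feats)[1] %/% 2
    pool <- array(0, c(side, side, dim(feats)[3]))
    for (k in seq_len(dim(feats)[3])) {
      f <- feats[, , k]
      pool[, , k] <- pmax(f[seq(1, nrow(f), 2), seq(1, ncol(f), 2)],
                          f[seq(2, nrow(f), 2), seq(1, ncol(f), 2)],
                          f[seq(1, nrow(f), 2), seq(2, ncol(f), 2)],
                          f[seq(2, nrow(f), 2), seq(2, ncol(f), 2)])
    }
    feats <- pool
  }
  cls <- which.max(out$probs) - 1L
  list(label = if (cls == 1L) "tumor" else "not_tumor",
       class = cls,
       score = max(out$probs),
       probs = as.numeric(out$probs),
       features = feature_stack(feats))
}

#' Predict tumor probabilities for a set of slices
#'
#' @param object a trained `tumor_cnn`.
#' @param slices list of matrices or 3D array of normalized slices.
#' @param ... unused.
#' @return tibble with `prob_not_tumor`, `prob_tumor`, `class`.
#' @export
predict.tumor_cnn <- function(object, slices, ...) {
  xs <- as_slice_cube(slices, object$input_side)
  probs <- cnn_forward_batch_cpp(xs, object$params)
  tibble(prob_not_tumor = probs[, 1], prob_tumor = probs[, 2],
         class = as.integer(probs[, 2] > probs[, 1]))
}

#' Save / load a trained network
#'
#' The parameters go to an RDS file and a JSON sidecar records the
#' architecture, scale, seed and training configuration.
#'
#' @param net a `tumor_cnn`.
#' @param path checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @return `path` (save) or the restored `tumor_cnn` (load).
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "tumor_cnn"))
  saveRDS(net, path)
  sidecar <- list(
    scale = net$scale, input_side = net$input_side, seed = net$seed,
    filters = net$spec$filters, trained = net$trained,
    train_config = if (!is.null(net$train_config))
      unclass(net$train_config) else NULL)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "tumor_cnn"))
  net
}

#' Export the per-epoch training history
#'
#' @param net a trained `tumor_cnn`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(net, path) {
  stopifnot(inherits(net, "tumor_cnn"), !is.null(net$history))
  write.csv(net$history, path, row.names = FALSE)
  invisible(path)
}
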