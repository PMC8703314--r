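#' Tidy the training history of a network
#'
#' @param x a trained `tumor_cnn`.
#' @param ... unused.
#' @return tibble with one row per epoch and metric: `epoch`, `lr`,
#'   `set` (train/val), `metric` (loss/accuracy), `value`.
#' @exportS3Method generics::tidy
tidy.tumor_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    stop("network has no training history", call. = FALSE)
  }
  h <- x$history
  dplyr::bind_rows(
    tibble(epoch = h$epoch, lr = h$lr, set = "train", metric = "loss",
           value = h$train_loss),
    tibble(epoch = h$epoch, lr = h$lr, set = "train", metric = "accuracy",
           value = h$train_acc),
    tibble(epoch = h$epoch, lr = h$lr, set = "validation", metric = "loss",
           value = h$val_loss),
    tibble(epoch = h$epoch, lr = h$lr, set = "validation",
           metric = "accuracy", value = h$val_acc))
}

#' One-row summary of a trained network
#'
#' @param x a `tumor_cnn`.
#' @param ... unused.
#' @return one-row tibble: scale, parameter count, epochs and final
#'   losses/accuracies.
#' @exportS3Method generics::glance
glance.tumor_cnn <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  h <- x$history
  tibble(scale = x$scale, n_params = np,
         epochs = if (is.null(h)) 0L else nrow(h),
         train_loss = if (is.null(h)) NA_real_ else h$train_loss[nrow(h)],
         train_acc = if (is.null(h)) NA_real_ else h$train_acc[nrow(h)],
         val_loss = if (is.null(h)) NA_real_ else h$val_loss[nrow(h)],
         val_acc = if (is.null(h)) NA_real_ else h$val_acc[nrow(h)])
}

#' Plot training curves
#'
#' Loss and accuracy per epoch for the train and validation sets.
#'
#' @param object a trained `tumor_cnn`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tumor_cnn <- function(object, ...) {
  d <- tidy.tumor_cnn(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a segmentation result
#'
#' Shows the overlay (slice plus colormapped saliency) with the final
#' mask outline implied by its extent; for a no-tumor result an empty
#' annotated panel is returned.
#'
#' @param object a `seg_result` from [segment_slice()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.seg_result <- function(object, ...) {
  if (!object$tumor_detected) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = sprintf("no tumor detected (%.2f)",
                                               object$score)) +
             ggplot2::theme_void())
  }
  rgb <- object$overlay
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  d <- expand.grid(row = seq_len(h), col = seq_len(w))
  d$fill <- grDevices::rgb(rgb[, , 1][as.matrix(d)],
                           rgb[, , 2][as.matrix(d)],
                           rgb[, , 3][as.matrix(d)])
  d$mask <- as.vector(unclass(object$mask) == 1)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_point(data = d[d$mask, ], shape = ".",
                        colour = "white", alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("tumor score %.2f, tau %.2f",
                                  object$score, object$tau))
}
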