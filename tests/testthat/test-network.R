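# expected per-layer output shapes of the full-width 18-layer stack on a
# 128 x 128 single-channel input (channels, height, width / fc units)
TABLE3_SHAPES <- list(
  list(1, "conv", 512L, 128L, 128L), list(2, "activation", 512L, 128L, 128L),
  list(3, "maxpool", 512L, 64L, 64L), list(4, "conv", 256L, 64L, 64L),
  list(5, "activation", 256L, 64L, 64L), list(6, "conv", 128L, 64L, 64L),
  list(7, "activation", 128L, 64L, 64L), list(8, "maxpool", 128L, 32L, 32L),
  list(9, "conv", 64L, 32L, 32L), list(10, "activation", 64L, 32L, 32L),
  list(11, "conv", 32L, 32L, 32L), list(12, "activation", 32L, 32L, 32L),
  list(13, "maxpool", 32L, 16L, 16L))

test_that("shape propagation reproduces the published layer table", {
  sh <- architecture_shapes(architecture_spec(1L), 128L)
  expect_identical(nrow(sh), 18L)
  for (row in TABLE3_SHAPES) {
    expect_identical(sh$type[row[[1]]], row[[2]])
    expect_identical(sh$channels[row[[1]]], row[[3]])
    expect_identical(sh$height[row[[1]]], row[[4]])
    expect_identical(sh$width[row[[1]]], row[[5]])
  }
  expect_identical(sh$units[sh$type == "flatten"], 8192L)
  expect_identical(sh$units[sh$type == "fc"], c(32L, 2L))
})

test_that("flatten width follows the filter scale", {
  expect_identical(flatten_width(architecture_spec(1L)), 8192L)
  expect_identical(flatten_width(architecture_spec(8L)), 1024L)
  expect_identical(architecture_spec(8L)$filters, c(64L, 32L, 16L, 8L, 4L))
  expect_error(architecture_spec(3L), "scale")
})

test_that("built networks have zero biases and a softmax output", {
  net <- test_net()
  for (l in seq(2, 14, by = 2)) expect_true(all(net$params[[l]] == 0))
  expect_identical(dim(net$params$W6), c(32L, 1024L))

  x <- matrix(rnorm(128 * 128), 128, 128)
  cls <- classify_slice(net, x)
  expect_lt(abs(sum(cls$probs) - 1), 1e-6)
  expect_true(all(cls$probs >= 0))
  expect_identical(dim(unclass(cls$features)), c(32L, 32L, 4L))
  expect_true(all(cls$features >= 0))

  # deterministic: same network + same input -> identical outputs
  cls2 <- classify_slice(net, x)
  expect_identical(cls$probs, cls2$probs)
  expect_identical(unclass(cls$features), unclass(cls2$features))

  pooled <- classify_slice(net, x, pooled = TRUE)
  expect_identical(dim(unclass(pooled$features)), c(16L, 16L, 4L))
  expect_error(classify_slice(net, matrix(0, 64, 64)), "128 x 128")
})

test_that("binary cross-entropy matches its closed forms and symmetry", {
  expect_lt(bce_loss(c(1, 0), c(1, 0)), 1e-6)
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    y <- sample(c(0, 1), 2)
    p <- runif(2)
    # independent elementwise evaluation
    ref <- -mean(y * log(pmin(pmax(p, 1e-7), 1 - 1e-7)) +
                   (1 - y) * log(1 - pmin(pmax(p, 1e-7), 1 - 1e-7)))
    expect_equal(bce_loss(y, p), ref, tolerance = 1e-9)
    expect_equal(bce_loss(y, p), bce_loss(1 - y, 1 - p), tolerance = 1e-12)
  }
  expect_error(bce_loss(c(1, 0), c(0.2, 0.3, 0.5)), "same shape")
})

test_that("the learning-rate schedule decays polynomially to zero", {
  expect_equal(lr_schedule(0, 45), 1e-4)
  expect_equal(lr_schedule(45, 45), 0)
  expect_equal(lr_schedule(22, 45), 1e-4 * (23 / 45)^0.9, tolerance = 1e-15)

  lrs <- lr_schedule(0:45, 45)
  expect_true(all(diff(lrs) < 0))
  expect_error(lr_schedule(46, 45), "0 <= e <= Ne")
})

test_that("labels derive from mask pixel counts", {
  masks <- list(matrix(0L, 4, 4),
                {
                  m <- matrix(0L, 4, 4); m[2, 2] <- 1L; m
                },
                {
                  m <- matrix(0L, 4, 4); m[1, 1:4] <- 1L; m
                })
  expect_identical(derive_labels(masks), c(0L, 1L, 1L))
  expect_identical(derive_labels(masks, tumor_pixel_min = 10L),
                   c(0L, 0L, 0L))
  expect_identical(derive_labels(masks[3], tumor_pixel_min = 4L), 1L)
})

test_that("classification metrics report flagged nulls, never silent zeros", {
  ident <- classification_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(ident$precision, 1)
  expect_equal(ident$recall, 1)
  expect_equal(ident$accuracy, 1)

  # TP=2 FP=1 FN=1 TN=6
  preds <- c(1, 1, 1, 0, rep(0, 6))
  labs <- c(1, 1, 0, 1, rep(0, 6))
  m <- classification_metrics(preds, labs)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$accuracy, 0.8)
  expect_identical(c(m$tp, m$fp, m$fn, m$tn), c(2L, 1L, 1L, 6L))

  deg <- classification_metrics(c(0, 0, 0), c(1, 1, 0))
  expect_true(is.na(deg$precision))
  expect_match(deg$flags, "precision_undefined")
  expect_equal(deg$recall, 0)

  expect_error(classification_metrics(numeric(0), numeric(0)), "empty")
})

test_that("ROC staircase and area match hand enumeration and pROC", {
  scores <- c(0.9, 0.8, 0.4, 0.3)
  labels <- c(1, 0, 1, 0)
  pts <- roc_points(scores, labels)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$tpr) >= 0) && all(diff(pts$fpr) >= 0))
  # hand enumeration: (0,0) (0,.5) (.5,.5) (.5,1) (1,1) -> AUC .75
  expect_equal(roc_auc(scores, labels), 0.75)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))))

  # perfect separation passes through (0, 1)
  p2 <- roc_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(p2$fpr == 0 & p2$tpr == 1))

  # all-identical scores: two-point diagonal
  p3 <- roc_points(rep(0.5, 4), c(1, 0, 1, 0))
  expect_equal(nrow(p3), 2L)
  expect_equal(p3$tpr, p3$fpr)
})

test_that("a short training run is bookkept, reproducible and error-checked", {
  set.seed(21)
  xs <- lapply(1:8, function(i)
    matrix(rnorm(128 * 128, mean = ifelse(i %% 2, 0, 0.5)), 128, 128))
  y <- rep(c(1L, 0L), 4)
  cfg <- train_config(epochs = 1, batch_size = 4, seed = 9,
                      split_ratio = 0.5)
  net <- train_network(test_net(), xs, y, cfg)
  expect_identical(nrow(net$history), 1L)
  expect_equal(net$history$lr[1], 1e-4)

  cfg2 <- train_config(epochs = 2, batch_size = 4, seed = 9,
                       split_ratio = 0.5)
  n1 <- train_network(test_net(), xs, y, cfg2)
  n2 <- train_network(test_net(), xs, y, cfg2)
  expect_equal(n1$history$train_loss, n2$history$train_loss,
               tolerance = 1e-9)
  expect_equal(tail(n1$history$val_loss, 1), tail(n2$history$val_loss, 1),
               tolerance = 1e-9)

  expect_error(train_network(test_net(), xs, rep(1L, 8), cfg),
               "both classes")
})

test_that("the scaled-down network separates Gaussian intensity classes", {
  set.seed(33)
  n <- 30
  xs <- lapply(1:n, function(i)
    matrix(rnorm(128 * 128, mean = ifelse(i %% 2, 0, 0.6)), 128, 128))
  y <- rep(c(1L, 0L), length.out = n)
  cfg <- train_config(epochs = 15, batch_size = 10, seed = 5)
  net <- train_network(build_network(scale = 8, seed = 11), xs, y, cfg)
  expect_gte(tail(net$history$train_acc, 1), 0.95)
})

test_that("checkpoints round-trip with a JSON sidecar", {
  d <- withr::local_tempdir()
  net <- test_net()
  p <- file.path(d, "net.rds")
  save_network(net, p)
  expect_true(file.exists(paste0(p, ".json")))
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(side$scale, 8)
  expect_equal(unlist(side$filters), c(64, 32, 16, 8, 4))
  back <- load_network(p)
  expect_equal(back$params, net$params)
})
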