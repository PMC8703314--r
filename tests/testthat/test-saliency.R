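test_that("spatial gradients are forward differences with zero trailing edge", {
  const <- matrix(5, 4, 4)
  g <- spatial_gradient(const)
  expect_true(all(g$H == 0) && all(g$V == 0))

  ramp <- matrix(rep(0:4, each = 3), 3, 5)   # X[i,j] = j - 1
  gr <- spatial_gradient(ramp)
  expect_true(all(gr$H[, 1:4] == 1))
  expect_true(all(gr$H[, 5] == 0))
  expect_true(all(gr$V == 0))

  # full hand evaluation of the 3x3 example [[0,1,3],[0,2,4],[1,1,1]]
  m <- matrix(c(0, 0, 1, 1, 2, 1, 3, 4, 1), 3, 3)
  gm <- spatial_gradient(m)
  expect_equal(gm$H, matrix(c(1, 2, 0, 2, 2, 0, 0, 0, 0), 3, 3,
                            byrow = TRUE))
  expect_equal(gm$V, matrix(c(0, 1, 1, 1, -1, -3, 0, 0, 0), 3, 3,
                            byrow = TRUE))

  expect_error(spatial_gradient(matrix(1, 1, 5)), "2 x 2")
})

test_that("gradient magnitude is the per-pixel Euclidean norm", {
  expect_true(all(gradient_magnitude(matrix(0, 3, 3),
                                     matrix(0, 3, 3)) == 0))
  expect_equal(gradient_magnitude(matrix(3, 1, 1), matrix(4, 1, 1))[1, 1], 5)

  set.seed(8)
  H <- matrix(rnorm(64), 8, 8); V <- matrix(rnorm(64), 8, 8)
  ref <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) ref[i, j] <- sqrt(H[i, j]^2 + V[i, j]^2)
  expect_equal(gradient_magnitude(H, V), ref, tolerance = 1e-15)

  expect_error(gradient_magnitude(H, V[1:4, ]), "same shape")
})

test_that("pooled weights are per-map mean and max of the magnitudes", {
  const_stack <- array(3, c(8, 8, 4))
  w0 <- pool_gradient_weights(gradient_stack(const_stack))
  expect_equal(w0$mean_vec, rep(0, 4))
  expect_equal(w0$max_vec, rep(0, 4))

  # one map with a single vertical step edge of height h
  stack <- array(0, c(8, 8, 2))
  stack[, 5:8, 1] <- 2.5
  w <- pool_gradient_weights(gradient_stack(stack))
  expect_equal(w$max_vec[1], 2.5)
  expect_equal(w$max_vec[2], 0)

  set.seed(10)
  rnd <- array(abs(rnorm(8 * 8 * 5)), c(8, 8, 5))
  wr <- pool_gradient_weights(gradient_stack(rnd))
  expect_true(all(wr$max_vec >= wr$mean_vec))
  expect_true(all(wr$mean_vec >= 0))
})

test_that("feature weighting is component-by-component", {
  set.seed(11)
  f <- feature_stack(array(abs(rnorm(8 * 8 * 4)), c(8, 8, 4)))

  unit <- structure(list(mean_vec = rep(1, 4), max_vec = rep(1, 4)),
                    class = "pooled_weights")
  expect_equal(unclass(weight_feature_maps(f, unit)), unclass(f),
               ignore_attr = TRUE)

  zero1 <- structure(list(mean_vec = c(0, 1, 1, 1), max_vec = rep(1, 4)),
                     class = "pooled_weights")
  expect_true(all(weight_feature_maps(f, zero1)[, , 1] == 0))

  w <- pool_gradient_weights(gradient_stack(f))
  out <- weight_feature_maps(f, w)
  ref <- array(0, dim(f))
  for (k in 1:4) for (i in 1:8) for (j in 1:8) {
    ref[i, j, k] <- f[i, j, k] * w$mean_vec[k] * w$max_vec[k]
  }
  expect_equal(unclass(out), ref, ignore_attr = TRUE, tolerance = 1e-15)

  bad <- structure(list(mean_vec = 1:3, max_vec = 1:3),
                   class = "pooled_weights")
  expect_error(weight_feature_maps(f, bad), "length")
})

test_that("the full weighted-mean map equals a naive triple-loop oracle", {
  set.seed(12)
  for (trial in 1:3) {
    f <- array(abs(rnorm(8 * 8 * 4)), c(8, 8, 4))
    # independent oracle: per-element loops all the way down
    H <- array(0, dim(f)); V <- array(0, dim(f))
    for (k in 1:4) for (i in 1:8) for (j in 1:8) {
      if (j < 8) H[i, j, k] <- f[i, j + 1, k] - f[i, j, k]
      if (i < 8) V[i, j, k] <- f[i + 1, j, k] - f[i, j, k]
    }
    mg <- sqrt(H^2 + V^2)
    mean_v <- apply(mg, 3, mean); max_v <- apply(mg, 3, max)
    ref <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8) {
      acc <- 0
      for (k in 1:4) acc <- acc + f[i, j, k] * mean_v[k] * max_v[k]
      ref[i, j] <- acc / 4
    }

    got <- mean_saliency(weight_feature_maps(
      feature_stack(f), pool_gradient_weights(gradient_stack(f))))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("mean_saliency averages the stack per pixel", {
  same <- array(rep(matrix(1:9, 3, 3), 4), c(3, 3, 4))
  expect_equal(mean_saliency(same), matrix(1:9, 3, 3))
  two <- array(c(rep(0, 9), rep(2, 9)), c(3, 3, 2))
  expect_equal(mean_saliency(two), matrix(1, 3, 3))
})

test_that("grayscale normalization clamps then scales to [0, 1]", {
  expect_true(all(normalize_to_grayscale(matrix(0, 4, 4)) == 0))
  g <- normalize_to_grayscale(matrix(c(-5, 0, 5, 10), 2, 2))
  expect_equal(as.numeric(unclass(g)), c(0, 0, 0.5, 1))
  expect_equal(max(normalize_to_grayscale(matrix(runif(16, 1, 10), 4))), 1)
  expect_error(normalize_to_grayscale(matrix(c(1, NA, 2, 3), 2)),
               "non-finite")
})

test_that("upsampling stays in range and keeps the hot spot localized", {
  m <- saliency_map(matrix(runif(32 * 32), 32, 32))
  expect_identical(unclass(upsample_saliency(m, c(32L, 32L))), unclass(m))

  const <- saliency_map(matrix(0.4, 32, 32))
  up <- upsample_saliency(const, c(128L, 128L))
  expect_equal(as.numeric(range(up)), c(0.4, 0.4), tolerance = 1e-12)

  hot <- matrix(0, 32, 32); hot[10, 20] <- 1
  uph <- upsample_saliency(saliency_map(hot), c(128L, 128L))
  am <- which(unclass(uph) == max(uph), arr.ind = TRUE)
  expect_true(all(am[, 1] >= 37 & am[, 1] <= 40))
  expect_true(all(am[, 2] >= 77 & am[, 2] <= 80))
  expect_gte(min(uph), 0)
  expect_lte(max(uph), 1)

  expect_error(upsample_saliency(m, c(16L, 16L)), ">= source")
})

test_that("the colormap is deterministic with documented endpoints", {
  m <- saliency_map(matrix(runif(64), 8, 8))
  rgb <- apply_colormap(m)
  expect_identical(dim(rgb), c(8L, 8L, 3L))
  expect_gte(min(rgb), 0)
  expect_lte(max(rgb), 1)

  ends <- apply_colormap(matrix(c(0, 1), 1, 2))
  expect_equal(as.numeric(ends[1, 1, ]), c(0, 0, 0.5))   # dark blue
  expect_equal(as.numeric(ends[1, 2, ]), c(0.5, 0, 0))   # dark red

  # equal gray values map to identical colors
  flat <- apply_colormap(matrix(0.3, 2, 2))
  expect_equal(flat[1, 1, ], flat[2, 2, ])
})

test_that("superimposition is additive, weighted and clipped", {
  base <- gray_to_rgb(matrix(runif(64), 8, 8))
  overlay <- apply_colormap(saliency_map(matrix(runif(64), 8, 8)))
  expect_equal(superimpose(base, overlay, alpha = 0), base)
  expect_equal(superimpose(base, array(0, dim(base)), alpha = 0.7), base)

  sat <- superimpose(array(0.9, c(4, 4, 3)), array(1, c(4, 4, 3)),
                     alpha = 1)
  expect_true(all(sat == 1))
  expect_error(superimpose(base, overlay[1:4, , , drop = FALSE], 0.4),
               "match")
})

test_that("threshold masks are monotone non-increasing in tau", {
  m <- saliency_map(matrix(c(0.2, 0.5, 0.9, 0.1), 2, 2))
  expect_equal(sum(threshold_mask(m, 0)), 4)
  expect_equal(sum(threshold_mask(m, 1)), 0)
  mk <- threshold_mask(saliency_map(matrix(c(0.2, 0.5, 0.9), 1, 3)), 0.5)
  expect_equal(as.integer(mk), c(0L, 1L, 1L))
  expect_equal(attr(mk, "threshold_used"), 0.5)

  set.seed(14)
  for (trial in 1:100) {
    sm <- saliency_map(matrix(runif(16 * 16), 16, 16))
    taus <- sort(runif(2))
    m1 <- threshold_mask(sm, taus[1])
    m2 <- threshold_mask(sm, taus[2])
    expect_true(all(m2 <= m1))
  }
})

test_that("the threshold sweep maximizes Dice with smallest-tau ties", {
  ref <- matrix(0L, 16, 16); ref[5:10, 5:10] <- 1L
  exact <- saliency_map(ref + 0)
  sw <- threshold_sweep(exact, ref)
  expect_equal(sw$best_tau, 0.33)          # all taus give DSC 1; tie rule
  expect_equal(max(sw$table$dsc_raw), 1)
  expect_false(sw$empty_ref)

  empty_ref <- matrix(0L, 16, 16)
  sw2 <- threshold_sweep(exact, empty_ref)
  expect_true(sw2$empty_ref)
  expect_equal(sw2$best_tau, 0.33)
  expect_true(all(sw2$table$dsc_raw == 0))

  # two plateaus at 0.4 and 0.8; reference = upper plateau
  plat <- matrix(0, 16, 16)
  plat[, 1:8] <- 0.4; plat[, 9:16] <- 0.8
  refp <- matrix(0L, 16, 16); refp[, 9:16] <- 1L
  swp <- threshold_sweep(saliency_map(plat), refp)
  expect_gt(swp$best_tau, 0.4)
  expect_lte(swp$best_tau, 0.8)
  expect_equal(max(swp$table$dsc_raw), 1)

  # default grid is 0.33..0.85 step 0.02, 27 members
  expect_length(default_taus(), 27L)
  expect_equal(range(default_taus()), c(0.33, 0.85))
})

test_that("segment_slice gates on the classifier and is reproducible", {
  ph <- phantom_input(seed = 77, tumor_prob = 1)

  no_net <- rig_network(test_net(), "not_tumor")
  res0 <- segment_slice(no_net, ph$x, mode = "fixed")
  expect_false(res0$tumor_detected)
  expect_null(res0$mask)

  yes_net <- rig_network(test_net(), "tumor")
  expect_error(segment_slice(yes_net, ph$x, mode = "sweep"),
               "reference")

  res <- segment_slice(yes_net, ph$x, mode = "sweep", ref = ph$mask)
  expect_true(res$tumor_detected)
  expect_s3_class(res$mask, "seg_mask")
  expect_identical(dim(unclass(res$mask)), c(128L, 128L))
  expect_identical(dim(res$overlay), c(128L, 128L, 3L))
  # argmax property: the chosen tau's Dice is at least every other one
  chosen <- as.numeric(dice(ph$mask, res$mask))
  expect_gte(chosen + 1e-12, max(res$sweep$dsc_post))

  res2 <- segment_slice(yes_net, ph$x, mode = "sweep", ref = ph$mask)
  expect_identical(unclass(res$mask), unclass(res2$mask))
  expect_identical(res$tau, res2$tau)
  expect_identical(unclass(res$saliency), unclass(res2$saliency))

  fx <- segment_slice(yes_net, ph$x, mode = "fixed", tau = 0.5)
  expect_equal(attr(fx$mask_raw, "threshold_used"), 0.5)
})
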