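test_that("z-score normalization centers and scales exactly", {
  expect_equal(zscore_normalize(matrix(c(0, 2), 1)), matrix(c(-1, 1), 1))

  set.seed(4)
  m <- matrix(runif(64 * 64, 10, 50), 64, 64)
  z <- zscore_normalize(m)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-6)

  # idempotent: normalizing a normalized image is the identity
  expect_equal(zscore_normalize(z), z, tolerance = 1e-6)

  expect_error(zscore_normalize(matrix(3, 4, 4)), "constant")
})

test_that("flips are involutions matching the hand-evaluated 2x2 case", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)         # [[1,2],[3,4]] by rows
  expect_equal(flip_h(m), matrix(c(2, 4, 1, 3), 2, 2))
  expect_equal(flip_v(m), matrix(c(3, 1, 4, 2), 2, 2))

  set.seed(1)
  r <- matrix(rnorm(35), 5, 7)
  expect_identical(flip_h(flip_h(r)), r)
  expect_identical(flip_v(flip_v(r)), r)

  sym <- r + flip_h(r)                      # symmetric under column reversal
  expect_equal(flip_h(sym), sym)
})

test_that("rotate90 is an exact quarter turn with +90 counter-clockwise", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)          # [[1,2],[3,4]]
  expect_equal(rotate90(m, 90), matrix(c(2, 1, 4, 3), 2, 2))  # [[2,4],[1,3]]

  set.seed(2)
  r <- matrix(rnorm(6 * 4), 6, 4)
  expect_identical(rotate90(rotate90(r, 90), -90), r)
  expect_identical(rotate90(rotate90(rotate90(rotate90(r, 90), 90), 90), 90),
                   r)
  expect_error(rotate90(r, 45), "\\+90 or -90")
})

test_that("shift translates with zero fill and composes to identity inside", {
  m <- matrix(rnorm(64 * 64), 64, 64)
  expect_identical(shift_slice(m, 0, 0), m)

  one <- matrix(0, 16, 16); one[5, 7] <- 9
  sh <- shift_slice(one, dx = 3, dy = 2)
  expect_equal(sh[7, 10], 9)
  expect_equal(sum(sh), 9)

  back <- shift_slice(shift_slice(m, 20, 20), -20, -20)
  kept <- 1:44                       # survives both translations
  expect_equal(back[kept, kept], m[kept, kept])
  expect_equal(sum(back[45:64, ]), 0)    # vacated trailing band
  expect_equal(sum(back[, 45:64]), 0)

  expect_error(shift_slice(m, 64, 0), "smaller than")
})

test_that("additive noise has the configured level and is seed-stable", {
  m <- matrix(runif(128 * 128), 128, 128)
  expect_identical(add_noise(m, 0), m)
  a <- add_noise(m, 0.05, seed = 42)
  b <- add_noise(m, 0.05, seed = 42)
  expect_identical(a, b)

  # CLT bound: sample mean of the added noise within 3 sigma / side
  sig <- 0.05 * diff(range(m))
  expect_lt(abs(mean(a - m)), 3 * sig / 128)
})

test_that("gaussian blur preserves constants and interior mass", {
  m <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(gaussian_blur(m, 0), m)
  expect_equal(gaussian_blur(matrix(7, 20, 20), 1.5), matrix(7, 20, 20),
               tolerance = 1e-12)

  # interior-supported content keeps its total intensity
  blob <- matrix(0, 64, 64)
  blob[28:36, 28:36] <- runif(81)
  bl <- gaussian_blur(blob, 2)
  expect_equal(sum(bl), sum(blob), tolerance = 1e-6 * sum(blob))
})

test_that("augmented datasets count, label and reproduce as configured", {
  cfg <- augment_config(seed = 11)
  empty <- build_augmented_dataset(list(), integer(0), cfg)
  expect_length(empty$slices, 0)

  slices <- lapply(1:3, function(i) matrix(rnorm(64 * 64), 64, 64))
  labels <- c(1L, 0L, 1L)
  all_out <- build_augmented_dataset(slices, labels, cfg, mode = "all")
  # 7 enabled transforms in "all" mode: flips, both rotations, shift,
  # noise, blur
  expect_length(all_out$slices, 3 * (1 + 7))
  expect_equal(all_out$labels, rep(labels, each = 8))

  s1 <- build_augmented_dataset(slices, labels, cfg, mode = "sample")
  s2 <- build_augmented_dataset(slices, labels, cfg, mode = "sample")
  expect_identical(s1$slices, s2$slices)
  expect_identical(s1$transform, s2$transform)

  expect_error(build_augmented_dataset(slices, c(1L, 0L), cfg),
               "one label per slice")
})

test_that("geometric transforms carry the paired mask, intensity ones do not", {
  px <- matrix(rnorm(32 * 32), 32, 32)
  mask <- matrix(0L, 32, 32); mask[10:14, 20:24] <- 1L
  cfg <- augment_config(seed = 3)
  out <- build_augmented_dataset(list(px), 1L, cfg, masks = list(mask),
                                 mode = "all")
  for (i in seq_along(out$slices)) {
    tname <- out$transform[i]
    expect_identical(dim(out$masks[[i]]), dim(mask))
    if (tname %in% c("original", "noise", "blur")) {
      expect_equal(out$masks[[i]], mask)
    } else if (tname == "flip_h") {
      expect_equal(out$masks[[i]],
                   matrix(as.integer(flip_h(mask)), 32, 32))
    } else if (tname == "rot_p90") {
      expect_equal(out$masks[[i]],
                   matrix(as.integer(rotate90(mask, 90)), 32, 32))
    }
    expect_true(all(out$masks[[i]] %in% c(0L, 1L)))
    expect_identical(dim(out$slices[[i]]), dim(px))
  }
})
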