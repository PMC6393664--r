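test_that("linear upsampling matches closed-form bilinear interpolation", {
  # constant image stays constant at any factor
  const <- matrix(3.2, 3, 5)
  for (f in c(2, 3, 4))
    expect_equal(linear_upsample(const, f), matrix(3.2, 3 * f, 5 * f),
                 tolerance = 1e-12)

  # hand-verified centre-aligned, edge-replicated interpolation
  up <- linear_upsample(matrix(c(0, 2), 1, 2), 2)
  expect_equal(up[1, ], c(0, 0.5, 1.5, 2), tolerance = 1e-12)

  # direct factor 4 against its own closed form on a 1D ramp
  ramp <- matrix(c(0, 4, 8), 1, 3)
  up4 <- linear_upsample(ramp, 4)
  src <- pmin(pmax(((1:12) - 0.5) / 4 - 0.5, 0), 2)
  expect_equal(up4[1, ], approx(0:2, c(0, 4, 8), xout = src)$y,
               tolerance = 1e-12)

  # stepwise factor 4 equals factor 2 applied twice (the multi-level
  # composition), which differs from the direct variant away from edges
  set.seed(4)
  x <- matrix(runif(12), 3, 4)
  twice <- linear_upsample(linear_upsample(x, 2), 2)
  expect_equal(linear_upsample(x, 4, method = "stepwise"), twice,
               tolerance = 1e-9)
  expect_error(linear_upsample(x, 2.5), "integer")
  expect_error(linear_upsample(x, 1), ">= 2")
})

test_that("block downsampling is the block arithmetic mean", {
  expect_equal(block_downsample(matrix(5, 6, 6), 2), matrix(5, 3, 3))
  expect_equal(block_downsample(matrix(c(1, 5, 3, 7), 2, 2), 2),
               matrix(4, 1, 1))
  set.seed(3)
  x <- matrix(runif(64), 8, 8)
  expect_equal(block_downsample(x, 4), oracle_block_mean(x, 4),
               tolerance = 1e-12)
  expect_error(block_downsample(x, 0), "positive integer")
  # pixel size bookkeeping
  img <- ion_image(x, 10)
  expect_equal(block_downsample(img, 4)$pixel_size_um, 40)
  expect_equal(linear_upsample(img, 2)$pixel_size_um, 5)
})

test_that("patch weights follow the Gaussian-SSD formula with class gating", {
  # constant histology, single class: all in-bounds weights equal
  cfg <- pbsr_config(patch_radius = 1, search_radius = 2, bandwidth_h = 0.2)
  w <- compute_weights(matrix(0.5, 7, 7), matrix(1L, 7, 7), c(4, 4), cfg)
  expect_true(all(w$weights == 1))
  expect_equal(w$sum, 25)

  # different class under the hard constraint: weight exactly 0
  mask <- matrix(1L, 7, 7); mask[4, 6] <- 2L
  w2 <- compute_weights(matrix(0.5, 7, 7), mask, c(4, 4), cfg)
  expect_identical(w2$weights[3, 5], 0)

  # hand-computed SSD: two 3x3 patches differing in one pixel by 0.2,
  # h = 0.2 -> weight exp(-1)
  hist5 <- matrix(0.5, 5, 5)
  hist5[1, 5] <- 0.7
  w3 <- compute_weights(hist5, matrix(1L, 5, 5), c(2, 2), cfg)
  expect_equal(w3$weights[3, 5], exp(-1), tolerance = 1e-12)

  # window positions beyond the border are NA
  wb <- compute_weights(matrix(0.5, 7, 7), matrix(1L, 7, 7), c(1, 1), cfg)
  expect_true(all(is.na(wb$weights[1:2, ])))
  expect_error(compute_weights(hist5, matrix(1L, 5, 5), c(9, 1), cfg),
               "center outside")
})

test_that("reconstruction sweep equals the brute-force quadruple-loop oracle", {
  set.seed(11)
  est <- matrix(runif(256), 16, 16)
  hist <- matrix(runif(256), 16, 16)
  mask <- matrix(sample(1:2, 256, replace = TRUE), 16, 16)
  for (h in list(0.3, NULL)) {  # fixed and auto bandwidth
    cfg <- pbsr_config(bandwidth_h = if (is.null(h)) "auto" else h)
    got <- reconstruct_step(est, hist, mask, cfg)
    want <- oracle_reconstruct(est, hist, mask, 1, 5, h)
    expect_lte(max(abs(got - want)), 1e-10)
  }
})

test_that("reconstruction fixes constants and class-wise-constant fields", {
  cfg <- pbsr_config()
  hist <- matrix(runif(144), 12, 12)
  mask <- matrix(rep(1:2, each = 72), 12, 12)
  # constant estimate: weighted mean of a constant
  expect_equal(reconstruct_step(matrix(1.5, 12, 12), hist, mask, cfg),
               matrix(1.5, 12, 12), tolerance = 1e-12)
  # class-wise constant with hard constraint: unchanged exactly
  est <- matrix(0, 12, 12); est[mask == 1] <- 0.3; est[mask == 2] <- 0.9
  expect_equal(reconstruct_step(est, hist, mask, cfg), est, tolerance = 1e-12)
})

test_that("mean correction enforces block-mean consistency", {
  cfg <- pbsr_config(clamp_negative = FALSE)
  set.seed(8)
  est <- matrix(runif(64), 8, 8)
  lr <- matrix(runif(16), 4, 4)
  corr <- mean_correction(est, lr, 2, cfg)
  expect_lte(max(abs(block_downsample(corr, 2) - lr)), 1e-9)

  # constant estimate c, lr = c + delta: every pixel becomes c + delta
  expect_equal(mean_correction(matrix(1, 4, 4), matrix(1.25, 2, 2), 2, cfg),
               matrix(1.25, 4, 4), tolerance = 1e-12)

  # explicit 4x4 ramp vs 2x2 lr, hand-computed additive correction
  est4 <- matrix(1:16, 4, 4) / 4
  lr2 <- matrix(c(1, 3, 2, 4), 2, 2)
  want <- est4
  for (i in 1:2) for (j in 1:2) {
    rows <- (2 * i - 1):(2 * i); cols <- (2 * j - 1):(2 * j)
    want[rows, cols] <- est4[rows, cols] + lr2[i, j] - mean(est4[rows, cols])
  }
  expect_equal(mean_correction(est4, lr2, 2, cfg), want, tolerance = 1e-12)
  expect_error(mean_correction(est4, matrix(1, 3, 3), 2, cfg), "dimensions")

  # clamping keeps intensities nonnegative
  cfg2 <- pbsr_config(clamp_negative = TRUE)
  neg <- mean_correction(matrix(0.01, 4, 4), matrix(-1, 2, 2), 2, cfg2)
  expect_true(all(neg >= 0))
})

test_that("run_level converges and honours the stopping rule", {
  # constant everything: fixed point in one iteration
  out <- run_level(matrix(2, 4, 4), matrix(0.5, 8, 8), matrix(1L, 8, 8))
  expect_equal(as.matrix(out), matrix(2, 8, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(nrow(attr(out, "trace")), 1L)

  # infinite tolerance: exactly one iteration
  b <- generate_phantom(phantom_config("glyph", seed = 5, hr_shape = c(32, 32)))
  h2 <- block_downsample(b$histology$values, 2)
  m2 <- pbsr:::majority_downsample(b$mask$labels, 2)
  cfg_inf <- pbsr_config(tolerance = Inf)
  out_inf <- run_level(b$lr_observed, h2, m2, cfg_inf)
  expect_identical(nrow(attr(out_inf, "trace")), 1L)

  # phantom level: finite decreasing-to-tolerance trace
  out2 <- run_level(b$lr_observed, h2, m2, pbsr_config())
  tr <- attr(out2, "trace")$relative_change
  expect_true(all(is.finite(tr)))
  expect_lte(tr[length(tr)], 1e-4)
  expect_s3_class(out2, "ion_image")
  expect_equal(out2$pixel_size_um, b$lr_observed$pixel_size_um / 2)
})

test_that("pipeline validates factors and tracks pixel sizes", {
  b <- generate_phantom(phantom_config("glyph", seed = 2, hr_shape = c(32, 32)))
  expect_error(run_pipeline(b$lr_observed, b$histology, b$mask,
                            target_factor = 1), "powers? of 2")
  expect_error(run_pipeline(b$lr_observed, b$histology, b$mask,
                            target_factor = 3), "powers? of 2")
  out <- run_pipeline(b$lr_observed, b$histology, b$mask, target_factor = 4)
  # 40 um LR at factor 4 -> 10 um, the design point of the glyph study
  expect_equal(out$pixel_size_um, 10)
  expect_identical(dim(out$values), dim(b$lr_observed$values) * 4L)
  # 10 um input at factor 4 -> 2.5 um (the duct use case)
  lr10 <- ion_image(b$lr_observed$values, 10)
  out2 <- run_pipeline(lr10, b$histology, b$mask, target_factor = 4)
  expect_equal(out2$pixel_size_um, 2.5)
})

test_that("pipeline accepts a transform for guides on a different grid", {
  b <- generate_phantom(phantom_config("glyph", seed = 9, hr_shape = c(32, 32)))
  shifted <- misalign_phantom(b, manual_transform(2, 0))
  # warping the guides back by the inverse realigns them for the pipeline
  out <- run_pipeline(shifted$lr_observed, shifted$histology, shifted$mask,
                      transform = transform_inverse(shifted$true_transform),
                      target_factor = 4)
  base <- run_pipeline(b$lr_observed, b$histology, b$mask, target_factor = 4)
  # away from the border the realigned guides give a near-identical result
  core <- 5:28
  expect_lte(mean(abs(out$values[core, core] - base$values[core, core])),
             0.02)
})

test_that("no-segmentation mode runs and degrades gracefully", {
  b <- generate_phantom(phantom_config("glyph", seed = 13, hr_shape = c(32, 32)))
  out <- run_pipeline(b$lr_observed, b$histology, mask = NULL,
                      target_factor = 4)
  expect_s3_class(out, "ion_image")
  expect_true(all(out$values >= 0))
})
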