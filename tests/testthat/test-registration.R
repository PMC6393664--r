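test_that("mutual information matches its definition and invariants", {
  set.seed(1); a <- matrix(runif(256 * 256), 256)
  set.seed(2); b <- matrix(runif(256 * 256), 256)

  # MI(a, a) equals the marginal entropy of a's binned histogram
  expect_equal(mutual_information(a, a, 16), entropy_binned(a, 16),
               tolerance = 1e-12)
  # independent noise: MI near zero
  expect_lte(mutual_information(a, b, 16), 0.01)
  # symmetry
  expect_lte(abs(mutual_information(a, b, 32) - mutual_information(b, a, 32)),
             1e-12)
  # positive affine remapping preserves bin assignments, hence MI
  expect_equal(mutual_information(a, 3 * b + 2, 16),
               mutual_information(a, b, 16), tolerance = 1e-12)
  # agreement with the brute-force joint-histogram oracle on a small pair
  a8 <- a[1:24, 1:24]; b8 <- b[1:24, 1:24]
  expect_equal(mutual_information(a8, b8, 8), oracle_mi(a8, b8, 8),
               tolerance = 1e-12)
  expect_error(mutual_information(a, b[1:10, 1:10]), "same shape")
})

test_that("manual transforms construct verbatim and validate scale", {
  t0 <- manual_transform(0, 0)
  expect_equal(t0$rotation_deg, 0)
  expect_equal(t0$scale, 1)
  expect_equal(c(t0$tx, t0$ty), c(0, 0))
  expect_error(manual_transform(0, 0, scale = -1), "scale")
  expect_error(manual_transform(0, 0, scale = 0), "scale")
})

test_that("warp implements centre-anchored bilinear resampling", {
  set.seed(3)
  x <- matrix(runif(64), 8, 8)
  # identity transform leaves the image unchanged
  expect_equal(warp(x, similarity_transform()), x, tolerance = 1e-12)

  # constant image stays constant inside the mapped footprint
  const <- matrix(2.5, 8, 8)
  w <- warp(const, similarity_transform(rotation_deg = 10, tx = 1))
  inside <- w != 0
  expect_true(all(abs(w[inside] - 2.5) < 1e-9))

  # 1D ramp, translation by half a pixel: interior samples are midpoints
  ramp <- matrix(c(0, 1, 2, 3), 1, 4)
  wr <- warp(ramp, manual_transform(0.5, 0))
  expect_equal(wr[1, 2:4], c(0.5, 1.5, 2.5), tolerance = 1e-12)

  # integer translation equals an array shift
  ws <- warp(x, manual_transform(2, 0))
  expect_equal(ws[, 3:8], x[, 1:6], tolerance = 1e-12)
  expect_true(all(ws[, 1:2] == 0))
  expect_error(warp(x, similarity_transform(), target_shape = c(0, 4)),
               "nonpositive")
})

test_that("warp round-trips through the inverse transform on smooth images", {
  n <- 48
  g <- outer(seq(0, 1, length.out = n), seq(0, 2, length.out = n),
             function(a, b) sin(3 * a) + cos(2 * b))
  g <- (g - min(g)) / (max(g) - min(g))
  t1 <- similarity_transform(rotation_deg = 4, scale = 1.03, tx = 2, ty = -1.5)
  back <- warp(warp(g, t1), transform_inverse(t1))
  core <- 9:(n - 8)
  err <- mean(abs(back[core, core] - g[core, core]))
  expect_lte(err, 0.02 * (max(g) - min(g)))
  # composing a transform with its inverse is the identity in coordinates
  ti <- transform_inverse(t1)
  tii <- transform_inverse(ti)
  expect_equal(tii$rotation_deg, t1$rotation_deg, tolerance = 1e-9)
  expect_equal(tii$scale, t1$scale, tolerance = 1e-9)
  expect_equal(c(tii$tx, tii$ty), c(t1$tx, t1$ty), tolerance = 1e-9)
})

test_that("label masks warp nearest-neighbour and stay integral", {
  m <- label_mask(matrix(sample(0:2, 64, replace = TRUE), 8, 8), 10)
  w <- warp(m, similarity_transform(rotation_deg = 7, tx = 0.4))
  expect_true(is.integer(w))
  expect_true(all(w %in% 0:2))
})

test_that("transform JSON serialization round-trips", {
  t1 <- similarity_transform(3.5, 1.02, -2.25, 0.75)
  f <- file.path(tempdir(), "t.json")
  write_transform(t1, f)
  t2 <- read_transform(f)
  expect_equal(t2, t1)
})

test_that("similarity registration recovers known transforms", {
  b <- generate_phantom(phantom_config("glyph", seed = 5))
  fixed <- b$histology$values

  # already aligned: transform within 0.5 px / 0.5 deg / 1% of identity
  est0 <- estimate_similarity(fixed, fixed)
  expect_lte(abs(est0$rotation_deg), 0.5)
  expect_lte(abs(est0$scale - 1), 0.01)
  expect_lte(abs(est0$tx), 0.5)
  expect_lte(abs(est0$ty), 0.5)

  # pure shift: inverse convention means shift (3, -2) recovers (-3, 2)
  mv <- warp(fixed, manual_transform(3, -2))
  est1 <- estimate_similarity(fixed, mv)
  expect_lte(abs(est1$tx - (-3)), 0.5)
  expect_lte(abs(est1$ty - 2), 0.5)

  # rotation + scale
  tr <- similarity_transform(rotation_deg = 5, scale = 1.05)
  mv2 <- warp(fixed, tr)
  est2 <- estimate_similarity(fixed, mv2)
  inv <- transform_inverse(tr)
  expect_lte(abs(est2$rotation_deg - inv$rotation_deg), 0.5)
  expect_lte(abs(est2$scale / inv$scale - 1), 0.01)

  # deterministic given the config
  est3 <- estimate_similarity(fixed, mv)
  expect_identical(unclass(est1)[c("rotation_deg", "scale", "tx", "ty")],
                   unclass(est3)[c("rotation_deg", "scale", "tx", "ty")])

  expect_error(estimate_similarity(matrix(1, 16, 16), fixed), "degenerate")
})
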