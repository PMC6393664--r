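test_that("ssim is 1 for identical images and symmetric", {
  set.seed(6)
  a <- matrix(runif(1024), 32, 32)
  b <- matrix(runif(1024), 32, 32)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_error(ssim(a, b[1:8, 1:8]), "same shape")
  # constant pair: zero joint dynamic range returns 1 by convention
  expect_equal(ssim(matrix(2, 4, 4), matrix(2, 4, 4)), 1)
})

test_that("ssim of an image and its negative is negative", {
  set.seed(2)
  a <- matrix(rnorm(1024), 32, 32)
  a <- a - mean(a)
  expect_lt(ssim(a, -a), 0)
})

test_that("ssim on a constant offset equals the luminance-term closed form", {
  set.seed(10)
  a <- matrix(runif(1024), 32, 32)
  off <- 0.1 * (max(a) - min(a))
  b <- a + off
  # independent evaluation: after joint min-max scaling the windows share
  # variance and covariance exactly, so local SSIM reduces to the luminance
  # term (2 mu_a mu_b + C1) / (mu_a^2 + mu_b^2 + C1); local means computed
  # here with a directly-convolved Gaussian window
  jmin <- min(a, b); jmax <- max(a, b)
  as <- (a - jmin) / (jmax - jmin); bs <- (b - jmin) / (jmax - jmin)
  rad <- 5; sig <- 1.5
  k1d <- exp(-((-rad):rad)^2 / (2 * sig^2)); k1d <- k1d / sum(k1d)
  kern <- outer(k1d, k1d)
  n <- 32
  local_mean <- function(m, r, c) {
    acc <- 0
    for (dr in -rad:rad) for (dc in -rad:rad) {
      rr <- mirror1(r + dr, n); cc <- mirror1(c + dc, n)
      acc <- acc + kern[dr + rad + 1, dc + rad + 1] * m[rr, cc]
    }
    acc
  }
  C1 <- 0.01^2
  vals <- matrix(0, n, n)
  for (r in 1:n) for (c in 1:n) {
    ma <- local_mean(as, r, c); mb <- local_mean(bs, r, c)
    vals[r, c] <- (2 * ma * mb + C1) / (ma^2 + mb^2 + C1)
  }
  expect_equal(ssim(a, b), mean(vals), tolerance = 1e-6)
})

test_that("Welch's t-test matches the formula oracle and t.test", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  got <- welch_t(x, y)
  want <- oracle_welch(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  ref <- stats::t.test(x, y)           # independent reference route
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  # identical samples: t = 0, p = 1
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # degenerate zero-variance cases
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t(c(3, 3), c(2, 2))$t, Inf)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")

  # two-sided p invariant under swapping the samples
  set.seed(20)
  x2 <- rnorm(15); y2 <- rnorm(9, 1, 2)
  expect_equal(welch_t(x2, y2)$p, welch_t(y2, x2)$p, tolerance = 1e-12)
})

test_that("Welch reduces to pooled Student's t for equal n and variances", {
  set.seed(21)
  x <- rnorm(12)
  y <- x * 1 + 5   # identical variance, equal n
  got <- welch_t(x, y)
  pooled <- stats::t.test(x, y, var.equal = TRUE)
  expect_lte(abs(got$t - unname(pooled$statistic)), 1e-12)
  expect_lte(abs(got$df - unname(pooled$parameter)), 1e-9)
})

test_that("Cohen's d follows the pooled-sd formula and sign convention", {
  # equal means: 0
  expect_equal(cohens_d(c(1, 2, 3), c(3, 2, 1)), 0)
  # unit mean difference with unit variances: d = 1
  x <- c(0, 1, 2); y <- c(-1, 0, 1)   # var 1 each, means 1 and 0
  expect_equal(cohens_d(x, y), 1, tolerance = 1e-12)
  # antisymmetry
  set.seed(22)
  x2 <- rnorm(30); y2 <- rnorm(25, 0.5)
  expect_equal(cohens_d(x2, y2), -cohens_d(y2, x2), tolerance = 1e-12)
  expect_equal(cohens_d(x2, y2), oracle_cohens_d(x2, y2), tolerance = 1e-12)
  # seeded sampling check against the generating effect size
  set.seed(9)
  a <- rnorm(100, 0.8, 1); b <- rnorm(100, 0, 1)
  expect_lte(abs(cohens_d(a, b) - 0.8), 0.2)
  expect_warning(d <- cohens_d(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_identical(d, -Inf)
})

test_that("ring construction matches a brute-force dilation oracle", {
  # single pixel, width 1: exactly the 8 neighbours
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  pair <- make_ring(m, 1)
  expect_identical(pair$area1, oracle_dilate(m) & !m)
  expect_identical(sum(pair$area1), 8L)

  # random masks: disjointness and oracle agreement for widths 1..3
  set.seed(14)
  rmask <- matrix(runif(144) < 0.2, 12, 12)
  sizes <- integer(3)
  for (w in 1:3) {
    p <- make_ring(rmask, w)
    expect_false(any(p$area1 & p$area2))
    d <- rmask
    for (i in seq_len(w)) d <- oracle_dilate(d)
    expect_identical(p$area1, d & !rmask)
    sizes[w] <- sum(p$area1)
  }
  # ring size monotone nondecreasing in width
  expect_true(all(diff(sizes) >= 0))

  # mask touching the border: clipped, no out-of-bounds pixels
  edge <- matrix(FALSE, 5, 5); edge[1, 1] <- TRUE
  pe <- make_ring(edge, 1)
  expect_identical(sum(pe$area1), 3L)
  expect_error(make_ring(matrix(FALSE, 3, 3)), "empty")

  # optional clip mask removes ring pixels outside the tissue
  clip <- matrix(TRUE, 7, 7); clip[, 5:7] <- FALSE
  pc <- make_ring(m, 1, clip = clip)
  expect_true(all(!pc$area1[, 5:7]))
})

test_that("intensity profiles sample rows and lines correctly", {
  expect_equal(intensity_profile(matrix(7, 3, 5), row = 2), rep(7, 5))
  set.seed(15)
  img <- matrix(runif(40), 5, 8)
  expect_equal(intensity_profile(img, row = 3), img[3, ])
  expect_error(intensity_profile(img, row = 9), "out of bounds")
  # diagonal line across a left-right ramp: linearly increasing samples
  ramp <- matrix(rep(0:7, each = 8), 8, 8)
  prof <- intensity_profile(ramp, from = c(1, 1), to = c(8, 8))
  d <- sqrt(2 * 49)
  expected <- (seq(0, 1, length.out = floor(d) + 1)) * 7
  expect_equal(prof, expected, tolerance = 1e-12)
})

test_that("checkerboard takes even tiles from a and odd from b", {
  a <- matrix(1, 4, 4); b <- matrix(2, 4, 4)
  expect_equal(checkerboard(a, a, 2), a)
  cb <- checkerboard(a, b, 2)
  want <- matrix(c(1, 1, 2, 2, 1, 1, 2, 2,
                   2, 2, 1, 1, 2, 2, 1, 1), 4, 4)
  expect_equal(cb, want)
  expect_equal(cb[1, 1], 1)  # tile (0,0) from a
  expect_equal(cb[1, 3], 2)  # tile (0,1) from b
  expect_error(checkerboard(a, matrix(1, 2, 2), 2), "same shape")
})

test_that("boxplot summaries use mean +/- 2.7 sd whiskers", {
  s <- boxplot_summary(1:5)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  # single value: quartiles collapse, no outliers
  s1 <- boxplot_summary(4.2)
  expect_equal(s1$median, 4.2)
  expect_equal(s1$q1, 4.2)
  expect_length(s1$outliers, 0)
  # standard normal: outlier fraction ~ P(|Z| > 2.7) ~ 0.007
  set.seed(4)
  z <- rnorm(10000)
  frac <- length(boxplot_summary(z)$outliers) / length(z)
  expect_lte(abs(frac - 2 * pnorm(-2.7)), 0.004)
})

test_that("evaluate_pair assembles a coherent report", {
  b <- generate_phantom(phantom_config("glyph", seed = 3, hr_shape = c(32, 32)))
  # the piecewise-constant truth has zero variance in both areas, so the
  # effect size degenerates to the documented -Inf sentinel with a warning
  expect_warning(
    rep <- evaluate_pair(b$truth_hr, b$truth_hr, b$mask$labels == 2,
                         clip = b$mask$labels > 0),
    "zero pooled variance")
  expect_equal(rep$ssim, 1, tolerance = 1e-12)
  expect_gte(rep$p_value, 0); expect_lte(rep$p_value, 1)
  # glyph is enriched relative to its ring: area1 - area2 convention -> d < 0
  expect_lt(rep$cohens_d, 0)
  expect_equal(rep$area2$median, 1.0)  # glyph class mean
})
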