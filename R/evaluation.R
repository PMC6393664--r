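#' Structural similarity index (SSIM)
#'
#' Mean of the local SSIM map computed with a Gaussian window. Because
#' low- and high-resolution MSI acquisitions have incomparable dynamic
#' ranges, the two images are min-max scaled *together* (one joint minimum
#' and maximum) before comparison, and the dynamic range `L` is that of the
#' joint pair; this choice is deliberate and affects absolute SSIM values.
#'
#' @param a,b Images of identical shape (matrices or image objects).
#' @param window_sigma Gaussian window standard deviation in pixels
#'   (default 1.5; the window is truncated at radius 5, i.e. 11x11).
#' @param k1,k2 SSIM stabilisation constants (defaults 0.01, 0.03);
#'   `C1 = (k1 L)^2`, `C2 = (k2 L)^2`.
#' @return SSIM in `[-1, 1]`; 1 only for identical images. A constant pair
#'   (zero joint dynamic range) returns 1 by convention.
#' @export
ssim <- function(a, b, window_sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  av <- as_values(a); bv <- as_values(b)
  if (!identical(dim(av), dim(bv)))
    stop("ssim: images must have the same shape", call. = FALSE)
  jmin <- min(av, bv); jmax <- max(av, bv)
  if (jmax <= jmin) return(1)
  av <- (av - jmin) / (jmax - jmin)
  bv <- (bv - jmin) / (jmax - jmin)
  L <- 1
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  mu_a <- gauss_filter(av, window_sigma)
  mu_b <- gauss_filter(bv, window_sigma)
  saa <- gauss_filter(av * av, window_sigma) - mu_a^2
  sbb <- gauss_filter(bv * bv, window_sigma) - mu_b^2
  sab <- gauss_filter(av * bv, window_sigma) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * sab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (saa + sbb + C2))
  mean(s)
}

# Separable Gaussian filter with mirror (symmetric) padding, truncated at
# radius 5 so the default sigma = 1.5 gives the usual 11x11 SSIM window.
gauss_filter <- function(x, sigma, radius = 5L) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_mirror <- function(m, kern) {
    n <- nrow(m); r <- (length(kern) - 1L) %/% 2L
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kern))
      out <- out + kern[j] * padded[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(conv_mirror(t(conv_mirror(x, k)), k))
}

#' Welch's t-test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t: each sample needs n >= 2", call. = FALSE)
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  dm <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (dm == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
    return(list(t = sign(dm) * Inf, df = nx + ny - 2, p = 0))
  }
  se2 <- vx / nx + vy / ny
  t <- dm / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cohen's d effect size
#'
#' Standardised mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled standard deviation
#' `sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#'
#' Sign convention: callers comparing a surrounding ring (area 1) against a
#' region of interest (area 2) pass `x = area1`, `y = area2`, so a
#' ROI-enriched signal yields a negative d.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return Cohen's d (possibly `Inf` with a warning if the pooled variance
#'   is zero but the means differ).
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("cohens_d: each sample needs n >= 2", call. = FALSE)
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  dm <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (dm == 0) return(0)
    warning("zero pooled variance with unequal means; returning Inf sentinel",
            call. = FALSE)
    return(sign(dm) * Inf)
  }
  dm / sqrt(sp2)
}

#' ROI and surrounding-ring area pair
#'
#' Builds the two pixel populations used for contrast statistics: area 2 is
#' the region of interest; area 1 is a ring of `width_px` pixels around it
#' (8-connectivity dilation minus the ROI), clipped to the image bounds and
#' optionally to a tissue mask.
#'
#' @param area2 Logical matrix: the ROI (e.g. glyph or gray-matter mask).
#' @param width_px Ring width in pixels, >= 1 (default 2; widths up to 3
#'   mirror the usual "2-3 pixel neighbourhood" choice).
#' @param clip Optional logical matrix; ring pixels outside it are dropped.
#' @return An object of class `area_pair`: list with logical matrices
#'   `area1` (ring) and `area2` (ROI); the two are disjoint.
#' @export
make_ring <- function(area2, width_px = 2L, clip = NULL) {
  area2 <- as.matrix(area2)
  if (!is.logical(area2)) area2 <- area2 != 0
  if (!any(area2)) stop("make_ring: empty ROI", call. = FALSE)
  width_px <- as.integer(width_px)
  if (width_px < 1L) stop("make_ring: width_px must be >= 1", call. = FALSE)
  dil <- area2
  for (i in seq_len(width_px)) dil <- dilate8(dil)
  ring <- dil & !area2
  if (!is.null(clip)) ring <- ring & (as.matrix(clip) != 0)
  structure(list(area1 = ring, area2 = area2), class = "area_pair")
}

# one 8-connectivity dilation via shifted copies
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    src_r <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
    shifted <- m[src_r, , drop = FALSE]
    if (dr == -1) shifted[nr, ] <- FALSE
    if (dr == 1) shifted[1, ] <- FALSE
    src_c <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
    shifted <- shifted[, src_c, drop = FALSE]
    if (dc == -1) shifted[, nc] <- FALSE
    if (dc == 1) shifted[, 1] <- FALSE
    out <- out | shifted
  }
  out
}

#' Intensity profile across an image
#'
#' Either the pixel values of one row (1-based), or bilinear samples at unit
#' spacing along an arbitrary line segment given as `(row, col)` endpoints.
#'
#' @param img Image (matrix or image object).
#' @param row 1-based row index, or `NULL` when `from`/`to` are given.
#' @param from,to Numeric `(row, col)` endpoints (1-based) of a line.
#' @return Numeric vector of sampled intensities.
#' @export
intensity_profile <- function(img, row = NULL, from = NULL, to = NULL) {
  x <- as_values(img)
  if (!is.null(row)) {
    row <- as.integer(row)
    if (row < 1L || row > nrow(x))
      stop("intensity_profile: row out of bounds", call. = FALSE)
    return(x[row, ])
  }
  if (is.null(from) || is.null(to))
    stop("intensity_profile: give 'row' or both 'from' and 'to'",
         call. = FALSE)
  len <- sqrt(sum((to - from)^2))
  n <- max(2L, floor(len) + 1L)
  tt <- seq(0, 1, length.out = n)
  rr <- from[1] + tt * (to[1] - from[1])
  cc <- from[2] + tt * (to[2] - from[2])
  if (any(rr < 1 | rr > nrow(x) | cc < 1 | cc > ncol(x)))
    stop("intensity_profile: line leaves the image", call. = FALSE)
  r0 <- pmin(floor(rr), nrow(x) - 1); c0 <- pmin(floor(cc), ncol(x) - 1)
  wr <- rr - r0; wc <- cc - c0
  (1 - wr) * (1 - wc) * x[cbind(r0, c0)] +
    (1 - wr) * wc * x[cbind(r0, c0 + 1)] +
    wr * (1 - wc) * x[cbind(r0 + 1, c0)] +
    wr * wc * x[cbind(r0 + 1, c0 + 1)]
}

#' Checkerboard composite of two images
#'
#' Alternating tiles from two aligned images, the standard display for
#' judging registration and reconstruction agreement: even-parity tiles
#' (counting from the top-left tile, which has parity 0) come from `a`,
#' odd-parity tiles from `b`.
#'
#' @param a,b Images of identical shape.
#' @param tile_px Tile edge length in pixels (>= 1).
#' @return A matrix of the common shape.
#' @export
checkerboard <- function(a, b, tile_px = 8L) {
  av <- as_values(a); bv <- as_values(b)
  if (!identical(dim(av), dim(bv)))
    stop("checkerboard: images must have the same shape", call. = FALSE)
  tile_px <- as.integer(tile_px)
  if (tile_px < 1L) stop("tile_px must be >= 1", call. = FALSE)
  pr <- (seq_len(nrow(av)) - 1L) %/% tile_px
  pc <- (seq_len(ncol(av)) - 1L) %/% tile_px
  odd <- outer(pr, pc, `+`) %% 2L == 1L
  out <- av
  out[odd] <- bv[odd]
  out
}

#' Boxplot summary statistics
#'
#' Median and quartiles (linear-interpolation quantile rule, `type = 7`),
#' whiskers at `mean +/- 2.7 * sd`, and the values beyond the whiskers as
#' outliers. For a single observation the whiskers collapse onto the value.
#'
#' @param values Numeric sample, n >= 1.
#' @return A list with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
boxplot_summary <- function(values) {
  if (length(values) < 1L) stop("boxplot_summary: empty sample", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  s <- if (length(values) > 1L) stats::sd(values) else 0
  lo <- mean(values) - 2.7 * s
  hi <- mean(values) + 2.7 * s
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = lo, whisker_hi = hi,
       outliers = values[values < lo | values > hi])
}

#' Full evaluation report for an upsampled image
#'
#' Computes the quantitative performance suite for one reconstructed image
#' against a reference: global SSIM, and ROI-contrast statistics (Welch's
#' t-test and Cohen's d between the surrounding ring, area 1, and the ROI,
#' area 2, evaluated on the *test* image's intensities) plus
#' median/quartile summaries per area.
#'
#' @param test Reconstructed image.
#' @param reference Reference image of the same shape.
#' @param roi Logical ROI matrix (area 2) on the same grid.
#' @param ring_width Ring width in pixels (default 2).
#' @param clip Optional tissue mask limiting the ring.
#' @return An object of class `eval_report`: list with `ssim`, `welch_t`,
#'   `welch_df`, `p_value`, `cohens_d`, `area1`, `area2` (each a
#'   [boxplot_summary()]-style list with median/q1/q3), and `n1`, `n2`.
#' @export
evaluate_pair <- function(test, reference, roi, ring_width = 2L, clip = NULL) {
  tv <- as_values(test)
  pair <- make_ring(roi, ring_width, clip = clip)
  x1 <- tv[pair$area1]
  x2 <- tv[pair$area2]
  wt <- welch_t(x1, x2)
  rep_area <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(median = q[2], q1 = q[1], q3 = q[3])
  }
  structure(
    list(ssim = ssim(test, reference),
         welch_t = wt$t, welch_df = wt$df, p_value = wt$p,
         cohens_d = cohens_d(x1, x2),
         area1 = rep_area(x1), area2 = rep_area(x2),
         n1 = length(x1), n2 = length(x2)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report\n  SSIM       %.4f\n", x$ssim))
  cat(sprintf("  Welch t    %.3f (df %.1f, p %.3g)\n",
              x$welch_t, x$welch_df, x$p_value))
  cat(sprintf("  Cohen's d  %.3f (area1 - area2)\n", x$cohens_d))
  cat(sprintf("  area1 (ring, n=%d)  %.3f (%.3f, %.3f)\n",
              x$n1, x$area1$median, x$area1$q1, x$area1$q3))
  cat(sprintf("  area2 (ROI,  n=%d)  %.3f (%.3f, %.3f)\n",
              x$n2, x$area2$median, x$area2$q1, x$area2$q3))
  invisible(x)
}
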