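#' Similarity transform
#'
#' Rotation, isotropic scale and translation mapping one image coordinate
#' frame (the "moving" image) into another (the "fixed"/target frame).
#'
#' Convention (documented so results are reproducible): pixel centres are
#' 0-based `(x = column, y = row)` coordinates; the map acts about the image
#' centres of both grids. A moving-pixel coordinate `m` maps to the fixed
#' frame as
#' `p = s * R(theta) * ((m - centre_mov) * k) + centre_fix + (tx, ty)`,
#' where `k` is the ratio of moving to fixed pixel size (1 when the grids
#' share a pixel size) and the translation is in fixed-frame pixels.
#'
#' @param rotation_deg Rotation angle in degrees (counter-clockwise in
#'   `(x, y)` with y pointing down the rows).
#' @param scale Isotropic scale factor (> 0).
#' @param tx,ty Translation in target-image pixels (x = columns, y = rows).
#'
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation_deg = 0, scale = 1, tx = 0, ty = 0) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("scale must be a single positive number", call. = FALSE)
  structure(
    list(rotation_deg = as.numeric(rotation_deg), scale = as.numeric(scale),
         tx = as.numeric(tx), ty = as.numeric(ty)),
    class = "similarity_transform"
  )
}

#' Manual similarity transform
#'
#' Constructs a transform verbatim from user-supplied parameters; covers the
#' manual-translation alignment workflow where the high- and low-resolution
#' acquisitions only need shifting onto one another.
#'
#' @param tx,ty Translation in target-image pixels.
#' @param rotation_deg Rotation in degrees (default 0).
#' @param scale Isotropic scale (default 1; must be > 0).
#' @return A [similarity_transform()].
#' @export
manual_transform <- function(tx, ty, rotation_deg = 0, scale = 1) {
  similarity_transform(rotation_deg, scale, tx, ty)
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "similarity_transform: rotation %.4g deg, scale %.6g, translation (%.4g, %.4g) px\n",
    x$rotation_deg, x$scale, x$tx, x$ty))
  invisible(x)
}

#' Invert a similarity transform
#'
#' Exact inverse for transforms between grids of equal shape and pixel size
#' (the centres cancel); composing a transform with its inverse is the
#' identity map on coordinates.
#'
#' @param t A [similarity_transform()].
#' @return The inverse [similarity_transform()].
#' @export
transform_inverse <- function(t) {
  th <- -t$rotation_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tr <- -(rot %*% c(t$tx, t$ty)) / t$scale
  similarity_transform(-t$rotation_deg, 1 / t$scale, tr[1], tr[2])
}

#' Serialize / deserialize a similarity transform
#'
#' JSON round trip carrying the parameters and a convention tag.
#'
#' @param t A [similarity_transform()].
#' @param path File path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns the [similarity_transform()].
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(
    list(rotation_deg = t$rotation_deg, scale = t$scale, tx = t$tx, ty = t$ty,
         convention = "moving-to-fixed, centre-anchored, 0-based pixel centres"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(j$rotation_deg, j$scale, j$tx, j$ty)
}

#' Warp an image under a similarity transform
#'
#' Resamples `image` (the moving image) onto a target grid: every target
#' pixel centre is mapped back through the inverse of `t` and sampled
#' bilinearly (or nearest-neighbour for label masks, which must stay
#' integral). Samples falling outside the moving image are 0.
#'
#' @param image Moving image (matrix, [ion_image()], [histology_image()], or
#'   [label_mask()]; masks force nearest-neighbour).
#' @param t A [similarity_transform()] mapping moving into target frame.
#' @param target_shape Integer `(rows, cols)` of the target grid; defaults
#'   to the moving image's shape.
#' @param target_pixel_size_um Pixel size of the target grid; defaults to the
#'   moving image's, giving `k = 1`.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return A matrix of the target shape (label masks return integer values).
#' @export
warp <- function(image, t, target_shape = NULL, target_pixel_size_um = NULL,
                 interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_mask <- inherits(image, "label_mask")
  if (is_mask) interpolation <- "nearest"
  x <- as_values(image)
  mov_px <- if (inherits(image, c("ion_image", "histology_image", "label_mask")))
    image$pixel_size_um else 1
  if (is.null(target_shape)) target_shape <- dim(x)
  target_shape <- as.integer(target_shape)
  if (any(target_shape <= 0)) stop("nonpositive target shape", call. = FALSE)
  if (is.null(target_pixel_size_um)) target_pixel_size_um <- mov_px
  k <- mov_px / target_pixel_size_um

  nr_t <- target_shape[1]; nc_t <- target_shape[2]
  nr_m <- nrow(x); nc_m <- ncol(x)
  cx_t <- (nc_t - 1) / 2; cy_t <- (nr_t - 1) / 2
  cx_m <- (nc_m - 1) / 2; cy_m <- (nr_m - 1) / 2

  # target pixel centres (0-based), x = col, y = row
  xs <- rep(0:(nc_t - 1), each = nr_t) - cx_t - t$tx
  ys <- rep(0:(nr_t - 1), times = nc_t) - cy_t - t$ty
  th <- -t$rotation_deg * pi / 180
  sx <- ((cos(th) * xs - sin(th) * ys) / t$scale) / k + cx_m
  sy <- ((sin(th) * xs + cos(th) * ys) / t$scale) / k + cy_m

  out <- numeric(nr_t * nc_t)
  if (interpolation == "nearest") {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 0 & ri <= nr_m - 1 & ci >= 0 & ci <= nc_m - 1
    out[ok] <- x[cbind(ri[ok] + 1, ci[ok] + 1)]
  } else {
    ok <- sx >= 0 & sx <= nc_m - 1 & sy >= 0 & sy <= nr_m - 1
    x0 <- floor(sx[ok]); y0 <- floor(sy[ok])
    wx <- sx[ok] - x0; wy <- sy[ok] - y0
    x1 <- pmin(x0 + 1, nc_m - 1); y1 <- pmin(y0 + 1, nr_m - 1)
    out[ok] <-
      (1 - wx) * (1 - wy) * x[cbind(y0 + 1, x0 + 1)] +
      wx * (1 - wy) * x[cbind(y0 + 1, x1 + 1)] +
      (1 - wx) * wy * x[cbind(y1 + 1, x0 + 1)] +
      wx * wy * x[cbind(y1 + 1, x1 + 1)]
  }
  m <- matrix(out, nr_t, nc_t)
  if (is_mask) storage.mode(m) <- "integer"
  m
}

#' Mutual information between two images
#'
#' MI (in nats) of the hard-binned joint histogram: each image is min-max
#' scaled to `[0, 1]` independently, assigned to `bins` equal-width bins, and
#' MI is computed from the `bins x bins` joint distribution.
#'
#' @param a,b Images (matrices or image objects) of identical shape.
#' @param bins Number of histogram bins per image (default 32, >= 2).
#' @return MI in nats (>= 0 up to floating point).
#' @export
mutual_information <- function(a, b, bins = 32L) {
  av <- as_values(a); bv <- as_values(b)
  if (!identical(dim(av), dim(bv)))
    stop("mutual_information: images must have the same shape", call. = FALSE)
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2", call. = FALSE)
  ia <- bin_index(av, bins)
  ib <- bin_index(bv, bins)
  joint <- tabulate(ia + (ib - 1L) * bins, nbins = bins * bins)
  n <- sum(joint)
  p <- joint / n
  pa <- rowSums(matrix(p, bins, bins))
  pb <- colSums(matrix(p, bins, bins))
  nz <- p > 0
  outer_p <- as.vector(outer(pa, pb))
  sum(p[nz] * log(p[nz] / outer_p[nz]))
}

bin_index <- function(x, bins) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(rep(1L, length(x)))
  i <- floor((as.vector(x) - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(i, bins)
}

#' Registration configuration
#'
#' Parameters of the multi-resolution mutual-information similarity
#' registration: a coarse-to-fine pyramid with a derivative-free coordinate
#' search per level (no MI gradient is needed for a 4-parameter problem),
#' refined by a Nelder-Mead polish at the finest level.
#'
#' @param pyramid_levels Number of resolution levels (default 3; level `i`
#'   works at downsampling factor `2^(levels - i)`).
#' @param iterations_per_level Cap on objective evaluations per level
#'   (default 1024).
#' @param histogram_bins Joint-histogram bins for MI (default 32).
#' @param step_px,step_deg,step_logscale Initial coordinate-search step sizes
#'   (translation in finest-grid pixels; rotation in degrees; scale on the
#'   log scale).
#' @param seed Retained for interface completeness; the search is
#'   deterministic and the seed only fixes any future stochastic sampler.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(pyramid_levels = 3L,
                                iterations_per_level = 1024L,
                                histogram_bins = 32L,
                                step_px = 4, step_deg = 4,
                                step_logscale = 0.04, seed = 1L) {
  if (pyramid_levels < 1L) stop("pyramid_levels must be >= 1", call. = FALSE)
  if (histogram_bins < 2L) stop("histogram_bins must be >= 2", call. = FALSE)
  structure(
    list(pyramid_levels = as.integer(pyramid_levels),
         iterations_per_level = as.integer(iterations_per_level),
         histogram_bins = as.integer(histogram_bins),
         step_px = step_px, step_deg = step_deg,
         step_logscale = step_logscale, seed = as.integer(seed)),
    class = "registration_config"
  )
}

#' Estimate the similarity transform aligning two images
#'
#' Multi-resolution maximisation of mutual information over rotation,
#' isotropic scale and translation. Deterministic given the configuration.
#' The returned transform maps `moving` into the `fixed` frame, i.e.
#' `warp(moving, t, dim(fixed), fixed_pixel_size)` aligns with `fixed`; if
#' `moving` was generated by warping `fixed` with a transform `g`, the
#' estimate recovers `inverse(g)` (inverse convention).
#'
#' @param fixed Fixed/target image ([histology_image()] or matrix).
#' @param moving Moving image ([ion_image()] or matrix).
#' @param cfg A [registration_config()].
#' @return A [similarity_transform()] with attributes `"mi"` (final MI in
#'   nats) and `"evaluations"` (objective evaluation count).
#' @export
estimate_similarity <- function(fixed, moving, cfg = registration_config()) {
  fv <- as_values(fixed); mv <- as_values(moving)
  if (stats::sd(fv) == 0 || stats::sd(mv) == 0)
    stop("degenerate (constant) input: estimate the transform manually ",
         "with manual_transform()", call. = FALSE)
  f_px <- if (inherits(fixed, c("histology_image", "ion_image")))
    fixed$pixel_size_um else 1
  m_px <- if (inherits(moving, c("histology_image", "ion_image")))
    moving$pixel_size_um else 1
  set.seed(cfg$seed)

  # pyramid: list of (fixed, moving, pixel sizes) from coarse to fine
  levels <- list()
  for (lev in seq_len(cfg$pyramid_levels)) {
    down <- 2L^(cfg$pyramid_levels - lev)
    fl <- fv; ml <- mv
    f_down <- 1L; m_down <- 1L
    if (down > 1L && min(dim(fv)) %/% down >= 8L) {
      fl <- as_values(block_downsample(fv, down)); f_down <- down
    }
    if (down > 1L && min(dim(mv)) %/% down >= 8L) {
      ml <- as_values(block_downsample(mv, down)); m_down <- down
    }
    levels[[lev]] <- list(fixed = fl, moving = ml,
                          f_px = f_px * f_down, m_px = m_px * m_down,
                          f_down = f_down)
  }

  n_eval <- 0L
  objective <- function(par, lev) {
    # par = (rotation_deg, log scale, tx, ty) in finest fixed-grid pixels
    n_eval <<- n_eval + 1L
    tr <- similarity_transform(par[1], exp(par[2]),
                               par[3] / lev$f_down, par[4] / lev$f_down)
    w <- warp_raw(lev$moving, tr, dim(lev$fixed), lev$m_px / lev$f_px)
    mutual_information(lev$fixed, w, cfg$histogram_bins)
  }

  par <- c(0, 0, 0, 0)
  for (lev in levels) {
    budget <- cfg$iterations_per_level
    steps <- c(cfg$step_deg, cfg$step_logscale,
               cfg$step_px * lev$f_down, cfg$step_px * lev$f_down)
    min_steps <- c(0.02, 2e-4, 0.02 * lev$f_down, 0.02 * lev$f_down)
    best <- objective(par, lev)
    used <- 1L
    while (used < budget && any(steps > min_steps)) {
      improved <- FALSE
      for (d in 1:4) {
        for (sgn in c(1, -1)) {
          cand <- par
          cand[d] <- cand[d] + sgn * steps[d]
          val <- objective(cand, lev)
          used <- used + 1L
          if (val > best + 1e-12) {
            best <- val; par <- cand; improved <- TRUE
            # greedy line continuation in the improving direction
            repeat {
              cand[d] <- cand[d] + sgn * steps[d]
              val <- objective(cand, lev)
              used <- used + 1L
              if (val > best + 1e-12) { best <- val; par <- cand }
              else break
              if (used >= budget) break
            }
            break
          }
        }
        if (used >= budget) break
      }
      if (!improved) steps <- steps / 2
    }
  }

  # Nelder-Mead polish at the finest level
  finest <- levels[[length(levels)]]
  polish <- stats::optim(par, function(p) -objective(p, finest),
                         method = "Nelder-Mead",
                         control = list(maxit = 300,
                                        parscale = c(0.5, 0.005, 0.25, 0.25),
                                        reltol = 1e-10))
  if (-polish$value >= objective(par, finest)) par <- polish$par

  out <- similarity_transform(par[1], exp(par[2]), par[3], par[4])
  attr(out, "mi") <- objective(par, finest)
  attr(out, "evaluations") <- n_eval
  out
}

# Internal warp on bare matrices with an explicit pixel-size ratio k
# (moving px / target px); bilinear, zeros outside.
warp_raw <- function(x, t, target_shape, k) {
  nr_t <- target_shape[1]; nc_t <- target_shape[2]
  nr_m <- nrow(x); nc_m <- ncol(x)
  cx_t <- (nc_t - 1) / 2; cy_t <- (nr_t - 1) / 2
  cx_m <- (nc_m - 1) / 2; cy_m <- (nr_m - 1) / 2
  xs <- rep(0:(nc_t - 1), each = nr_t) - cx_t - t$tx
  ys <- rep(0:(nr_t - 1), times = nc_t) - cy_t - t$ty
  th <- -t$rotation_deg * pi / 180
  sx <- ((cos(th) * xs - sin(th) * ys) / t$scale) / k + cx_m
  sy <- ((sin(th) * xs + cos(th) * ys) / t$scale) / k + cy_m
  out <- numeric(nr_t * nc_t)
  ok <- sx >= 0 & sx <= nc_m - 1 & sy >= 0 & sy <= nr_m - 1
  x0 <- floor(sx[ok]); y0 <- floor(sy[ok])
  wx <- sx[ok] - x0; wy <- sy[ok] - y0
  x1 <- pmin(x0 + 1, nc_m - 1); y1 <- pmin(y0 + 1, nr_m - 1)
  out[ok] <-
    (1 - wx) * (1 - wy) * x[cbind(y0 + 1, x0 + 1)] +
    wx * (1 - wy) * x[cbind(y0 + 1, x1 + 1)] +
    (1 - wx) * wy * x[cbind(y1 + 1, x0 + 1)] +
    wx * wy * x[cbind(y1 + 1, x1 + 1)]
  matrix(out, nr_t, nc_t)
}
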