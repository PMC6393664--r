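#' PBSR configuration
#'
#' All free parameters of the patch-based super-resolution algorithm.
#'
#' @param patch_radius Patch radius in pixels on the high-resolution grid;
#'   the guide patch is `(2 * patch_radius + 1)^2`. Default 1 (3x3 patches).
#' @param search_radius Search-window radius in pixels; candidate neighbours
#'   come from the `(2 * search_radius + 1)^2` window. Default 5 (11x11).
#' @param bandwidth_h Gaussian kernel bandwidth in histology-intensity units,
#'   or `"auto"` (default): the noise-proportional bandwidth
#'   `h = sigma * sqrt(2 * beta * N)` with `beta = 2`, `N` the patch pixel
#'   count, and `sigma` the standard deviation of guide intensities within
#'   each pixel's search window (the result floored at 1e-6). This scaling
#'   keeps same-class patch distances of order `h^2`, so within-class
#'   averaging stays strong (fast fixed-point convergence) while the
#'   segmentation constraint handles cross-class discrimination. Larger h
#'   averages more aggressively across dissimilar patches.
#' @param class_constraint `"hard"` (default): neighbours whose segmentation
#'   label differs from the centre get weight exactly 0. `"soft"`: their
#'   weight is multiplied by `exp(-beta)`.
#' @param beta Penalty for the soft class constraint. Default 3.
#' @param level_factor Upsampling factor per level; the pipeline doubles
#'   resolution per level. Fixed at 2.
#' @param tolerance Relative-change convergence threshold (L2 norm of the
#'   update over the L2 norm of the previous estimate). Default 1e-4.
#' @param max_iterations Iteration cap per level. Default 50.
#' @param clamp_negative Clamp negative intensities to zero after each
#'   mean-correction step (a single pass; block-mean consistency is then
#'   approximate wherever clamping fired). Default TRUE.
#'
#' @return An object of class `pbsr_config`.
#' @export
pbsr_config <- function(patch_radius = 1L, search_radius = 5L,
                        bandwidth_h = "auto",
                        class_constraint = c("hard", "soft"), beta = 3,
                        level_factor = 2L, tolerance = 1e-4,
                        max_iterations = 50L, clamp_negative = TRUE) {
  class_constraint <- match.arg(class_constraint)
  patch_radius <- as.integer(patch_radius)
  search_radius <- as.integer(search_radius)
  if (patch_radius < 1L) stop("patch_radius must be >= 1", call. = FALSE)
  if (search_radius < patch_radius)
    stop("search_radius must be >= patch_radius", call. = FALSE)
  if (!identical(bandwidth_h, "auto")) {
    bandwidth_h <- as.numeric(bandwidth_h)
    if (!is.finite(bandwidth_h) || bandwidth_h <= 0)
      stop("bandwidth_h must be positive or \"auto\"", call. = FALSE)
  }
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0", call. = FALSE)
  if (as.integer(level_factor) != 2L)
    stop("level_factor is fixed at 2 (resolution doubles per level)",
         call. = FALSE)
  structure(
    list(patch_radius = patch_radius, search_radius = search_radius,
         bandwidth_h = bandwidth_h, class_constraint = class_constraint,
         beta = as.numeric(beta), level_factor = 2L,
         tolerance = as.numeric(tolerance),
         max_iterations = as.integer(max_iterations),
         clamp_negative = isTRUE(clamp_negative)),
    class = "pbsr_config"
  )
}

# 1D bilinear interpolation matrix (n_out x n_in) with pixel-centre
# alignment and edge replication: output pixel i (0-based) samples input
# coordinate (i + 0.5) / factor - 0.5, clamped to [0, n_in - 1].
interp_matrix <- function(n_in, factor) {
  n_out <- n_in * factor
  src <- (seq_len(n_out) - 0.5) / factor - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  lo <- floor(src)
  w <- src - lo
  hi <- pmin(lo + 1, n_in - 1)
  m <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  m[cbind(idx, lo + 1)] <- m[cbind(idx, lo + 1)] + (1 - w)
  m[cbind(idx, hi + 1)] <- m[cbind(idx, hi + 1)] + w
  m
}

#' Bilinear upsampling of an ion image
#'
#' Linear-interpolation (LI) upsampling with pixel-centre alignment and edge
#' replication. This is both the initialisation of each PBSR level and the
#' stand-alone LI baseline the method is compared against.
#'
#' @param img An [ion_image()] (or bare matrix).
#' @param factor Integer upsampling factor >= 2.
#' @param method `"direct"` (default): a single bilinear interpolation at
#'   `factor`. `"stepwise"`: repeated factor-2 interpolation (requires
#'   `factor` to be a power of 2); this is the composition the multi-level
#'   pipeline effectively applies and differs slightly from `"direct"` for
#'   factors > 2.
#'
#' @return An upsampled image of the same class as the input; pixel size is
#'   divided by `factor`.
#' @export
linear_upsample <- function(img, factor, method = c("direct", "stepwise")) {
  method <- match.arg(method)
  if (length(factor) != 1L || !is.finite(factor) || factor != round(factor))
    stop("factor must be a single integer", call. = FALSE)
  factor <- as.integer(factor)
  if (factor < 2L) stop("factor must be >= 2", call. = FALSE)
  f0 <- factor
  x <- as_values(img)
  if (method == "stepwise") {
    if (log2(factor) != round(log2(factor)))
      stop("stepwise upsampling requires a power-of-2 factor", call. = FALSE)
    while (factor > 1L) {
      x <- interp_matrix(nrow(x), 2L) %*% x %*% t(interp_matrix(ncol(x), 2L))
      factor <- factor %/% 2L
    }
  } else {
    x <- interp_matrix(nrow(x), factor) %*% x %*%
      t(interp_matrix(ncol(x), factor))
  }
  x[x < 0] <- 0  # guard against tiny negative round-off
  rewrap(img, x, scale_pixel = 1 / f0)
}

# Rebuild an image-like object around new values, optionally scaling the
# pixel size; bare matrices stay bare matrices.
rewrap <- function(template, values, scale_pixel = 1) {
  if (inherits(template, "ion_image")) {
    ion_image(values, template$pixel_size_um * scale_pixel,
              template$mz_center, template$mz_tolerance)
  } else if (inherits(template, "histology_image")) {
    histology_image(pmin(pmax(values, 0), 1),
                    template$pixel_size_um * scale_pixel)
  } else {
    values
  }
}

#' Block-mean downsampling
#'
#' Each low-resolution pixel is the arithmetic mean of its `factor x factor`
#' high-resolution block. This is the forward (measurement) operator whose
#' adjoint structure the mean-correction step enforces. Dimensions not
#' divisible by `factor` are first padded by edge replication to the next
#' multiple (documented policy), so every output pixel is a full-block mean.
#'
#' @param img An [ion_image()] (or bare matrix).
#' @param factor Positive integer downsampling factor.
#' @return The downsampled image; pixel size is multiplied by `factor`.
#' @export
block_downsample <- function(img, factor) {
  if (length(factor) != 1L || !is.finite(factor) || factor != round(factor) ||
      factor <= 0)
    stop("factor must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  x <- as_values(img)
  x <- pad_to_multiple(x, factor)
  nr <- nrow(x) %/% factor
  nc <- ncol(x) %/% factor
  # mean over blocks via row then column aggregation
  ar <- matrix(0, nr, nrow(x))
  ar[cbind(rep(seq_len(nr), each = factor), seq_len(nrow(x)))] <- 1 / factor
  ac <- matrix(0, nc, ncol(x))
  ac[cbind(rep(seq_len(nc), each = factor), seq_len(ncol(x)))] <- 1 / factor
  rewrap(img, ar %*% x %*% t(ac), scale_pixel = factor)
}

pad_to_multiple <- function(x, factor) {
  nr <- nrow(x); nc <- ncol(x)
  pr <- (factor - nr %% factor) %% factor
  pc <- (factor - nc %% factor) %% factor
  if (pr > 0) x <- rbind(x, x[rep(nr, pr), , drop = FALSE])
  if (pc > 0) x <- cbind(x, x[, rep(nc, pc), drop = FALSE])
  x
}

# Majority-vote block downsampling for label masks; ties break to the
# smallest label so the result is deterministic.
majority_downsample <- function(labels, factor) {
  labels <- pad_to_multiple(labels, factor)
  nr <- nrow(labels) %/% factor
  nc <- ncol(labels) %/% factor
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1) * factor + 1):(i * factor)
    for (j in seq_len(nc)) {
      block <- labels[rows, ((j - 1) * factor + 1):(j * factor)]
      tab <- table(block)
      out[i, j] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  out
}

check_guides <- function(est_values, hist, mask) {
  h <- as_values(hist)
  m <- if (is.null(mask)) matrix(1L, nrow(h), ncol(h)) else as_values(mask)
  storage.mode(m) <- "integer"
  if (!identical(dim(h), dim(est_values)) || !identical(dim(m), dim(est_values)))
    stop("histology, mask and estimate must share one grid", call. = FALSE)
  list(hist = h, mask = m)
}

#' Patch weights around one centre pixel
#'
#' Returns the unnormalised weight field over the search window centred at
#' one high-resolution pixel: `w_j = exp(-||P(i) - P(j)||^2 / h^2)` where
#' `P(.)` is the guide-image patch (SSD over `(2p+1)^2` pixels, mirror-padded
#' at borders). Under the hard class constraint, neighbours with a different
#' segmentation label get weight 0; under the soft constraint their weight is
#' multiplied by `exp(-beta)`. Window positions outside the image are `NA`.
#'
#' @param hist Guide [histology_image()] (or matrix) on the reconstruction grid.
#' @param mask [label_mask()] (or integer matrix) on the same grid; `NULL`
#'   means a single class everywhere (no-segmentation mode).
#' @param center Integer `(row, col)`, 1-based, of the centre pixel.
#' @param cfg A [pbsr_config()].
#' @return A list with `weights` (a `(2s+1) x (2s+1)` matrix) and `sum`
#'   (sum of non-`NA` weights).
#' @export
compute_weights <- function(hist, mask = NULL, center, cfg = pbsr_config()) {
  h <- as_values(hist)
  m <- if (is.null(mask)) matrix(1L, nrow(h), ncol(h)) else as_values(mask)
  storage.mode(m) <- "integer"
  r <- as.integer(center[1]); c <- as.integer(center[2])
  if (r < 1L || r > nrow(h) || c < 1L || c > ncol(h))
    stop("center outside image", call. = FALSE)
  h_auto <- identical(cfg$bandwidth_h, "auto")
  w <- pbsr_weights_cpp(h, m, r - 1L, c - 1L, cfg$patch_radius,
                        cfg$search_radius,
                        if (h_auto) 0 else cfg$bandwidth_h, h_auto,
                        cfg$class_constraint == "hard", cfg$beta)
  list(weights = w, sum = sum(w, na.rm = TRUE))
}

#' One reconstruction sweep
#'
#' Replaces every pixel of the current high-resolution estimate by the
#' weighted mean of the previous estimate over its search window, weights
#' from guide-patch similarity and segmentation agreement (see
#' [compute_weights()]). Pixels whose weight sum is zero keep their previous
#' value.
#'
#' @param estimate Current estimate ([ion_image()] or matrix).
#' @param hist,mask Guides on the same grid (`mask = NULL` for single-class).
#' @param cfg A [pbsr_config()].
#' @return The updated estimate, same class as `estimate`.
#' @export
reconstruct_step <- function(estimate, hist, mask = NULL, cfg = pbsr_config()) {
  x <- as_values(estimate)
  g <- check_guides(x, hist, mask)
  h_auto <- identical(cfg$bandwidth_h, "auto")
  out <- pbsr_reconstruct_cpp(x, g$hist, g$mask, cfg$patch_radius,
                              cfg$search_radius,
                              if (h_auto) 0 else cfg$bandwidth_h, h_auto,
                              cfg$class_constraint == "hard", cfg$beta)
  rewrap(estimate, out)
}

#' Mean correction against the low-resolution measurement
#'
#' Rectifies the high-resolution estimate toward the measured low-resolution
#' image: for every LR pixel, the difference between its measured value and
#' the block mean of the estimate is added to every HR pixel of that block,
#' so block means match the measurement exactly afterwards. With
#' `cfg$clamp_negative`, negative results are then set to zero in a single
#' pass, which makes the consistency approximate only where clamping fired.
#'
#' @param estimate High-resolution estimate; dimensions must equal
#'   `dim(lr) * factor`.
#' @param lr The low-resolution measured image.
#' @param factor Integer block factor.
#' @param cfg A [pbsr_config()].
#' @return The corrected estimate, same class as `estimate`.
#' @export
mean_correction <- function(estimate, lr, factor, cfg = pbsr_config()) {
  x <- as_values(estimate)
  l <- as_values(lr)
  factor <- as.integer(factor)
  if (!identical(dim(x), dim(l) * factor))
    stop("estimate dimensions must equal lr dimensions times factor",
         call. = FALSE)
  bm <- as_values(block_downsample(x, factor))
  corr <- (l - bm)[rep(seq_len(nrow(l)), each = factor),
                   rep(seq_len(ncol(l)), each = factor)]
  out <- x + corr
  if (cfg$clamp_negative) out[out < 0] <- 0
  rewrap(estimate, out)
}

#' One doubling level of PBSR
#'
#' Initialises with bilinear upsampling at factor 2, then alternates
#' reconstruction sweeps and mean correction until the relative L2 change
#' between successive corrected estimates drops to `cfg$tolerance` or
#' `cfg$max_iterations` is reached (a warning, not an error).
#'
#' @param lr Low-resolution [ion_image()] (or matrix) for this level.
#' @param hist,mask Guides at exactly twice the resolution of `lr`.
#' @param cfg A [pbsr_config()].
#' @return The converged estimate with attribute `"trace"`: a data frame of
#'   `iteration` and `relative_change`. With `clamp_negative = TRUE`
#'   (default) an [ion_image()] input yields an [ion_image()]; with clamping
#'   disabled (a diagnostic mode in which block-mean consistency with `lr`
#'   is exact) the raw matrix is returned, since small negative intensities
#'   may then survive.
#' @export
run_level <- function(lr, hist, mask = NULL, cfg = pbsr_config()) {
  init <- as_values(linear_upsample(lr, 2L))
  g <- check_guides(init, hist, mask)
  xv <- iterate_level(init, as_values(lr), 2L, g$hist, g$mask, cfg)
  out <- if (cfg$clamp_negative)
    rewrap(lr, as_values(xv), scale_pixel = 0.5) else as_values(xv)
  attr(out, "trace") <- attr(xv, "trace")
  out
}

# Reconstruction / mean-correction loop: iterates from `init` (on the grid
# `dim(lr_anchor) * factor`) until the relative L2 change between successive
# corrected estimates reaches cfg$tolerance.
iterate_level <- function(init, lr_anchor, factor, hist, mask, cfg) {
  g <- check_guides(init, hist, mask)
  xv <- init
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(cfg$max_iterations)) {
    prev <- xv
    xv <- as_values(reconstruct_step(xv, g$hist, g$mask, cfg))
    xv <- as_values(mean_correction(xv, lr_anchor, factor, cfg))
    rel <- sqrt(sum((xv - prev)^2)) / max(sqrt(sum(prev^2)), 1e-300)
    trace[it] <- rel
    if (rel <= cfg$tolerance) { converged <- TRUE; break }
  }
  if (!converged && is.finite(cfg$tolerance))
    warning(sprintf(
      "PBSR level did not converge in %d iterations (last relative change %.3g)",
      cfg$max_iterations, trace[length(trace)]), call. = FALSE)
  attr(xv, "trace") <- data.frame(iteration = seq_along(trace),
                                  relative_change = trace)
  xv
}

#' Full PBSR upsampling pipeline
#'
#' Aligns the guides with the MSI frame (when `transform` is given, the
#' histology and mask are warped onto the target high-resolution grid of the
#' low-resolution image; the mask nearest-neighbour), then doubles the
#' resolution `log2(target_factor)` times. Guides for intermediate levels
#' are obtained from the full-resolution guides by block-mean (histology) and
#' majority-vote (mask) downsampling. Each level initialises from the
#' previous level's output (bilinearly doubled), but mean correction is
#' always anchored to the *measured* low-resolution image at the cumulative
#' block factor: anchoring to an intermediate estimate instead would freeze
#' in the boundary errors of the coarsened segmentation and forfeit exact
#' recovery of piecewise-constant signals.
#'
#' @param lr Measured low-resolution [ion_image()].
#' @param hist [histology_image()] guide.
#' @param mask [label_mask()] on the histology grid, or `NULL` to run without
#'   segmentations (supported, but reconstruction quality is degraded).
#' @param transform Optional [similarity_transform()] mapping the histology
#'   frame into the target grid; `NULL` means the guides are already on the
#'   target grid (`dim(lr) * target_factor`).
#' @param target_factor Total upsampling factor; must be a power of 2 (>= 2).
#' @param cfg A [pbsr_config()].
#' @return The high-resolution [ion_image()] (pixel size
#'   `lr$pixel_size_um / target_factor`) with attribute `"convergence"`, a
#'   data frame of `level`, `iteration`, `relative_change`. As for
#'   [run_level()], disabling `clamp_negative` returns the raw matrix.
#' @export
run_pipeline <- function(lr, hist, mask = NULL, transform = NULL,
                         target_factor = 4L, cfg = pbsr_config()) {
  if (length(target_factor) != 1L || !is.finite(target_factor) ||
      target_factor != round(target_factor) || target_factor < 2 ||
      log2(target_factor) != round(log2(target_factor)))
    stop("target_factor must be a power of 2 and >= 2 (supported: 2, 4, 8, ...)",
         call. = FALSE)
  target_factor <- as.integer(target_factor)
  n_levels <- as.integer(round(log2(target_factor)))
  lrv <- as_values(lr)
  target_dim <- dim(lrv) * target_factor
  target_px <- (if (inherits(lr, "ion_image")) lr$pixel_size_um else 1) /
    target_factor

  hv <- as_values(hist)
  mv <- if (is.null(mask)) NULL else as_values(mask)
  if (!is.null(transform)) {
    hv <- warp(hv, transform, target_shape = target_dim)
    if (!is.null(mv))
      mv <- warp(mv, transform, target_shape = target_dim,
                 interpolation = "nearest")
  }
  if (!identical(dim(hv), target_dim))
    stop("guides must be on the target grid (dim(lr) * target_factor); ",
         "supply 'transform' to warp them", call. = FALSE)
  if (is.null(mv)) mv <- matrix(1L, target_dim[1], target_dim[2])
  storage.mode(mv) <- "integer"

  est <- lrv
  traces <- list()
  for (lev in seq_len(n_levels)) {
    down <- 2L^(n_levels - lev)
    h_lev <- if (down > 1L) as_values(block_downsample(hv, down)) else hv
    m_lev <- if (down > 1L) majority_downsample(mv, down) else mv
    init <- as_values(linear_upsample(est, 2L))
    est <- iterate_level(init, lrv, 2L^lev, h_lev, m_lev, cfg)
    tr <- attr(est, "trace")
    tr$level <- lev
    traces[[lev]] <- tr
    est <- as_values(est)
  }
  out <- if (inherits(lr, "ion_image") && cfg$clamp_negative) {
    ion_image(est, target_px, lr$mz_center, lr$mz_tolerance)
  } else est
  conv <- do.call(rbind, traces)
  attr(out, "convergence") <- conv[, c("level", "iteration", "relative_change")]
  out
}
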