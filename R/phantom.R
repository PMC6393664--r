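#' Phantom generator configuration
#'
#' Seeded configuration for paired ground-truth high-resolution ion images,
#' histology guides, segmentation masks, and noisy low-resolution
#' observations. Three scenarios emulate the archetypal study designs:
#'
#' * `"glyph"` — letter-like bars micro-dissected out of a tissue field
#'   (classes: 0 background, 1 tissue, 2 glyph); bar width defaults to 1.5
#'   low-resolution pixels, the sub-LR-pixel stress case. Factor 4
#'   (40 um -> 10 um style).
#' * `"cortex"` — a folded two-class band structure (sinusoidal white/gray
#'   boundary) inside a foreground blob (classes: 0 background, 1 white
#'   matter, 2 gray matter). Factor 8 (80 um -> 10 um style).
#' * `"duct"` — an annulus of epithelium around a lumen embedded in
#'   parenchyma (classes: 0 parenchyma/background, 1 epithelium, 2 lumen);
#'   the marker concentrates in the epithelial ring. Factor 4.
#'
#' The histology image is a per-class contrast map plus seeded Gaussian
#' texture that is independent of the ion intensities within each class:
#' histology contributes structure, not signal.
#'
#' @param scenario One of `"glyph"`, `"cortex"`, `"duct"`.
#' @param hr_shape High-resolution grid `(rows, cols)`; must be divisible by
#'   `factor`.
#' @param factor Downsampling factor between HR truth and LR observation
#'   (4 or 8).
#' @param class_means Named numeric vector of mean ion intensity per class
#'   label (names `"0"`, `"1"`, `"2"`); `NULL` takes scenario defaults.
#' @param noise `"gaussian"` (additive, `noise_sd`) or `"poisson"`
#'   (counts at `poisson_scale` per intensity unit, rescaled back).
#' @param noise_sd Gaussian noise standard deviation on the LR observation
#'   (default 0.05).
#' @param poisson_scale Expected counts per unit intensity for Poisson noise
#'   (default 200).
#' @param histology_texture_sd Within-class histology texture SD
#'   (default 0.05).
#' @param histology_class_contrast Luminance separation spanned by the
#'   classes in the histology guide (default 0.5).
#' @param lr_pixel_size_um Physical pixel size of the LR grid (default 40).
#' @param glyph_thickness_lr_px Bar thickness in LR pixels for the glyph
#'   scenario (default 1.5).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(scenario = c("glyph", "cortex", "duct"),
                           hr_shape = NULL, factor = NULL,
                           class_means = NULL,
                           noise = c("gaussian", "poisson"),
                           noise_sd = 0.05, poisson_scale = 200,
                           histology_texture_sd = 0.05,
                           histology_class_contrast = 0.5,
                           lr_pixel_size_um = 40,
                           glyph_thickness_lr_px = 1.5,
                           seed = 42L) {
  scenario <- match.arg(scenario)
  noise <- match.arg(noise)
  if (is.null(factor))
    factor <- switch(scenario, glyph = 4L, cortex = 8L, duct = 4L)
  factor <- as.integer(factor)
  if (!factor %in% c(4L, 8L))
    stop("factor must be 4 or 8", call. = FALSE)
  if (is.null(hr_shape))
    hr_shape <- switch(scenario, glyph = c(64L, 64L), cortex = c(96L, 96L),
                       duct = c(64L, 64L))
  hr_shape <- as.integer(hr_shape)
  if (any(hr_shape %% factor != 0L))
    stop("hr_shape must be divisible by factor", call. = FALSE)
  if (is.null(class_means))
    class_means <- switch(scenario,
      glyph = c("0" = 0.05, "1" = 0.35, "2" = 1.0),
      cortex = c("0" = 0.02, "1" = 0.30, "2" = 0.80),
      duct = c("0" = 0.15, "1" = 0.90, "2" = 0.05))
  if (any(class_means < 0)) stop("class means must be >= 0", call. = FALSE)
  structure(
    list(scenario = scenario, hr_shape = hr_shape, factor = factor,
         class_means = class_means, noise = noise, noise_sd = noise_sd,
         poisson_scale = poisson_scale,
         histology_texture_sd = histology_texture_sd,
         histology_class_contrast = histology_class_contrast,
         lr_pixel_size_um = lr_pixel_size_um,
         glyph_thickness_lr_px = glyph_thickness_lr_px,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

scenario_labels <- function(cfg) {
  nr <- cfg$hr_shape[1]; nc <- cfg$hr_shape[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  labels <- matrix(0L, nr, nc)
  if (cfg$scenario == "glyph") {
    # tissue field with a margin of ~1 LR pixel of background
    m <- cfg$factor
    tissue <- rr > m & rr <= nr - m & cc > m & cc <= nc - m
    labels[tissue] <- 1L
    # letter-like strokes: two verticals, one horizontal, one diagonal
    th <- max(1L, as.integer(round(cfg$glyph_thickness_lr_px * cfg$factor)))
    v1 <- as.integer(round(nc * 0.30)); v2 <- as.integer(round(nc * 0.62))
    hrow <- as.integer(round(nr * 0.5))
    bar <- (cc >= v1 & cc < v1 + th) | (cc >= v2 & cc < v2 + th) |
      (rr >= hrow & rr < hrow + th & cc >= v1 & cc < v2 + th)
    diag_band <- abs((rr - nr * 0.25) - (cc - nc * 0.70)) < th / 2 &
      cc >= nc * 0.70 & cc <= nc * 0.88
    glyph <- (bar | diag_band) & tissue & rr > nr * 0.15 & rr < nr * 0.85
    labels[glyph] <- 2L
  } else if (cfg$scenario == "cortex") {
    # foreground ellipse; sinusoidal white/gray boundary folding inside it
    e <- ((rr - nr / 2) / (0.42 * nr))^2 + ((cc - nc / 2) / (0.45 * nc))^2 <= 1
    boundary <- nr / 2 + 0.18 * nr * sin(2 * pi * 2.3 * cc / nc)
    gray <- e & (rr > boundary)
    labels[e] <- 1L
    labels[gray] <- 2L
  } else {
    # duct: epithelium annulus around a lumen, off-centre in parenchyma
    d <- sqrt((rr - nr * 0.52)^2 + (cc - nc * 0.48)^2)
    r_out <- 0.28 * min(nr, nc); r_in <- 0.17 * min(nr, nc)
    labels[d <= r_out] <- 1L
    labels[d <= r_in] <- 2L
  }
  labels
}

#' Generate a synthetic phantom bundle
#'
#' Builds the scenario geometry, sets the ground-truth HR ion image to the
#' class means (`truth_hr = class_means[label]`, exactly piecewise
#' constant), renders the histology guide as class contrast plus seeded
#' texture, and observes `lr_observed = block_downsample(truth_hr, factor)`
#' plus noise (clamped at 0). With zero noise the block means of the truth
#' equal the observation exactly.
#'
#' @param cfg A [phantom_config()].
#' @return An object of class `phantom_bundle`: list with `truth_hr`
#'   ([ion_image()]), `histology` ([histology_image()]), `mask`
#'   ([label_mask()]), `lr_observed` ([ion_image()]), `config` (the echoed
#'   generating parameters), and `true_transform` (identity until
#'   [misalign_phantom()] is applied).
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  labels <- scenario_labels(cfg)
  present <- as.character(sort(unique(as.vector(labels))))
  missing <- setdiff(present, names(cfg$class_means))
  if (length(missing) > 0)
    stop("class_means missing labels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  hr_px <- cfg$lr_pixel_size_um / cfg$factor
  truth <- matrix(cfg$class_means[as.character(labels)],
                  nrow(labels), ncol(labels))

  set.seed(cfg$seed)
  # histology: classes spread over [base, base + contrast], plus texture
  n_classes <- length(present)
  levels <- 0.2 + cfg$histology_class_contrast *
    (seq_len(n_classes) - 1) / max(1, n_classes - 1)
  names(levels) <- present
  hist_v <- matrix(levels[as.character(labels)], nrow(labels), ncol(labels)) +
    stats::rnorm(length(labels), sd = cfg$histology_texture_sd)
  hist_v <- pmin(pmax(hist_v, 0), 1)

  lr_clean <- as_values(block_downsample(truth, cfg$factor))
  if (cfg$noise == "gaussian") {
    lr_obs <- lr_clean + if (cfg$noise_sd > 0)
      stats::rnorm(length(lr_clean), sd = cfg$noise_sd) else 0
  } else {
    lr_obs <- stats::rpois(length(lr_clean),
                           lambda = lr_clean * cfg$poisson_scale) /
      cfg$poisson_scale
  }
  lr_obs <- matrix(pmax(lr_obs, 0), nrow(lr_clean), ncol(lr_clean))

  class_names <- switch(cfg$scenario,
    glyph = c("0" = "background", "1" = "tissue", "2" = "glyph"),
    cortex = c("0" = "background", "1" = "white_matter", "2" = "gray_matter"),
    duct = c("0" = "parenchyma", "1" = "duct_epithelium", "2" = "duct_lumen"))

  structure(
    list(truth_hr = ion_image(truth, hr_px),
         histology = histology_image(hist_v, hr_px),
         mask = label_mask(labels, hr_px, class_names),
         lr_observed = ion_image(lr_obs, cfg$lr_pixel_size_um),
         config = cfg,
         true_transform = similarity_transform()),
    class = "phantom_bundle"
  )
}

#' Misalign a phantom's guides
#'
#' Warps the histology (bilinear) and mask (nearest-neighbour) by a
#' similarity transform, recording the ground-truth transform so
#' registration recovery can be tested end to end: registering the warped
#' histology back onto the original recovers `transform_inverse(t)`.
#'
#' @param bundle A [generate_phantom()] result.
#' @param t A [similarity_transform()].
#' @return The bundle with warped `histology`/`mask` and `true_transform = t`.
#' @export
misalign_phantom <- function(bundle, t) {
  h <- warp(bundle$histology, t)
  m <- warp(bundle$mask, t)
  bundle$histology <- histology_image(pmin(pmax(h, 0), 1),
                                      bundle$histology$pixel_size_um)
  bundle$mask <- label_mask(m, bundle$mask$pixel_size_um,
                            bundle$mask$class_names)
  bundle$true_transform <- t
  bundle
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("phantom_bundle (%s): HR %d x %d at %g um, LR %d x %d at %g um, seed %d\n",
              x$config$scenario, nrow(x$truth_hr$values),
              ncol(x$truth_hr$values), x$truth_hr$pixel_size_um,
              nrow(x$lr_observed$values), ncol(x$lr_observed$values),
              x$lr_observed$pixel_size_um, x$config$seed))
  invisible(x)
}
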