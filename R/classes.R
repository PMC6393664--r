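#' Ion image
#'
#' A 2D grid of nonnegative relative ion intensities for a single m/z window,
#' together with its physical pixel size.
#'
#' @param values Numeric matrix of finite, nonnegative intensities.
#' @param pixel_size_um Physical pixel edge length in micrometres (> 0).
#' @param mz_center Centre of the extracted m/z window in Da (may be `NA` for
#'   synthetic or derived images).
#' @param mz_tolerance Half-width of the m/z window in Da (may be `NA`).
#'
#' @return An object of class `ion_image`: a list with elements `values`,
#'   `pixel_size_um`, `mz_center`, `mz_tolerance`.
#' @export
ion_image <- function(values, pixel_size_um, mz_center = NA_real_,
                      mz_tolerance = NA_real_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("ion_image: 'values' must be at least 1x1", call. = FALSE)
  if (!all(is.finite(values)))
    stop("ion_image: 'values' must be finite", call. = FALSE)
  if (any(values < 0))
    stop("ion_image: 'values' must be nonnegative", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("ion_image: 'pixel_size_um' must be a single positive number",
         call. = FALSE)
  structure(
    list(values = values, pixel_size_um = as.numeric(pixel_size_um),
         mz_center = as.numeric(mz_center),
         mz_tolerance = as.numeric(mz_tolerance)),
    class = "ion_image"
  )
}

#' Histology image
#'
#' High-resolution grayscale (luminance) raster in `[0, 1]` used as the guide
#' for patch-based reconstruction. RGB microscopy images are collapsed to
#' luminance by [read_raster()] before they become a `histology_image`.
#'
#' @param values Numeric matrix with values in `[0, 1]`.
#' @param pixel_size_um Physical pixel edge length in micrometres (> 0).
#'
#' @return An object of class `histology_image`.
#' @export
histology_image <- function(values, pixel_size_um) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("histology_image: 'values' must be at least 1x1", call. = FALSE)
  if (!all(is.finite(values)))
    stop("histology_image: 'values' must be finite", call. = FALSE)
  if (any(values < 0 | values > 1))
    stop("histology_image: 'values' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("histology_image: 'pixel_size_um' must be a single positive number",
         call. = FALSE)
  structure(
    list(values = values, pixel_size_um = as.numeric(pixel_size_um)),
    class = "histology_image"
  )
}

#' Segmentation label mask
#'
#' Integer class labels on the histology grid. Label 0 is reserved for
#' background; positive labels are tissue classes (e.g. tissue/glyph,
#' white/gray matter, duct epithelium/lumen).
#'
#' @param labels Integer matrix of small nonnegative labels.
#' @param pixel_size_um Physical pixel edge length in micrometres (> 0).
#' @param class_names Optional named character vector mapping labels
#'   (as names, e.g. `"0"`, `"1"`) to class names.
#'
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size_um, class_names = NULL) {
  labels <- as.matrix(labels)
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stop("label_mask: 'labels' must be nonnegative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("label_mask: 'pixel_size_um' must be a single positive number",
         call. = FALSE)
  structure(
    list(labels = labels, pixel_size_um = as.numeric(pixel_size_um),
         class_names = class_names),
    class = "label_mask"
  )
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("ion_image: %d x %d px at %g um/px", nrow(x$values),
              ncol(x$values), x$pixel_size_um))
  if (is.finite(x$mz_center))
    cat(sprintf(", m/z %.4f +/- %.4f", x$mz_center, x$mz_tolerance))
  cat(sprintf("\n  intensity range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.histology_image <- function(x, ...) {
  cat(sprintf("histology_image: %d x %d px at %g um/px, range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  labs <- sort(unique(as.vector(x$labels)))
  cat(sprintf("label_mask: %d x %d px at %g um/px, labels {%s}\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um,
              paste(labs, collapse = ", ")))
  invisible(x)
}

#' Extract the value matrix of an image object
#'
#' @param x An [ion_image()], [histology_image()], or [label_mask()].
#' @param ... Unused.
#' @return The underlying matrix (labels for masks).
#' @export
as.matrix.ion_image <- function(x, ...) x$values

#' @rdname as.matrix.ion_image
#' @export
as.matrix.histology_image <- function(x, ...) x$values

#' @rdname as.matrix.ion_image
#' @export
as.matrix.label_mask <- function(x, ...) x$labels

# Coerce matrix-or-image arguments to a bare matrix of values.
as_values <- function(x) {
  if (inherits(x, c("ion_image", "histology_image"))) return(x$values)
  if (inherits(x, "label_mask")) return(x$labels)
  as.matrix(x)
}
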