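# Minimal single-strip, little-endian, 32-bit-float grayscale TIFF writer.
# The tiff package reads IEEE-float TIFFs but only writes integer samples,
# which cannot hold ion intensities losslessly; writing the float variant
# ourselves keeps the round trip exact for float32-representable data.
write_float_tiff <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nr <- nrow(values); nc <- ncol(values)
  n_entries <- 10L
  data_offset <- 8L + 2L + n_entries * 12L + 4L
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)  # 3 = SHORT, 4 = LONG
  }
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)
  w2(n_entries)
  entry(256L, 4L, 1L, nc)             # ImageWidth
  entry(257L, 4L, 1L, nr)             # ImageLength
  entry(258L, 3L, 1L, 32L)            # BitsPerSample
  entry(259L, 3L, 1L, 1L)             # Compression: none
  entry(262L, 3L, 1L, 1L)             # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_offset)    # StripOffsets
  entry(277L, 3L, 1L, 1L)             # SamplesPerPixel
  entry(278L, 4L, 1L, nr)             # RowsPerStrip
  entry(279L, 4L, 1L, 4L * nr * nc)   # StripByteCounts
  entry(339L, 3L, 1L, 3L)             # SampleFormat: IEEE float
  w4(0L)                              # no further IFD
  writeBin(as.double(as.vector(t(values))), con, size = 4, endian = "little")
  invisible(path)
}

#' Read and write raster images with a JSON sidecar
#'
#' Ion images and histology are stored as single-channel 32-bit float TIFF
#' (read back with the tiff package); label masks as 8-bit PNG. The pixel
#' size, image kind, and any m/z window metadata travel in a sidecar JSON
#' file at `<path>.json`. The round trip is lossless for data representable
#' in 32-bit floats.
#'
#' RGB histology is collapsed to luminance with the Rec. 601 weights
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel is ignored; more than 4
#' channels is an error.
#'
#' @param image An [ion_image()], [histology_image()], or [label_mask()].
#' @param path Output path (`.tif`/`.tiff` for images, `.png` for masks).
#' @return `write_raster` returns `path` invisibly.
#' @export
write_raster <- function(image, path) {
  sidecar <- paste0(path, ".json")
  if (inherits(image, "label_mask")) {
    if (max(image$labels) > 255)
      stop("write_raster: labels above 255 are not supported in 8-bit masks",
           call. = FALSE)
    png::writePNG(image$labels / 255, path)
    jsonlite::write_json(
      list(kind = "mask", pixel_size_um = image$pixel_size_um,
           class_names = as.list(image$class_names)),
      sidecar, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  write_float_tiff(as_values(image), path)
  meta <- list(kind = if (inherits(image, "histology_image")) "histology"
               else "ion",
               pixel_size_um = image$pixel_size_um)
  if (inherits(image, "ion_image") && is.finite(image$mz_center)) {
    meta$mz_center <- image$mz_center
    meta$mz_tolerance <- image$mz_tolerance
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @param pixel_size_um Fallback pixel size when no sidecar exists.
#' @param kind Force the returned type: `"ion"`, `"histology"`, or `"mask"`;
#'   default taken from the sidecar, falling back to `"ion"` for TIFF and
#'   `"mask"` for PNG.
#' @return `read_raster` returns an [ion_image()], [histology_image()], or
#'   [label_mask()] according to `kind`.
#' @export
read_raster <- function(path, pixel_size_um = NULL, kind = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  if (is.null(kind))
    kind <- if (!is.null(meta$kind)) meta$kind
            else if (is_png) "mask" else "ion"
  px <- if (!is.null(meta$pixel_size_um)) meta$pixel_size_um
        else pixel_size_um
  if (is.null(px))
    stop("no pixel size: no sidecar found and pixel_size_um not given",
         call. = FALSE)
  v <- if (is_png) png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(v)) == 3) {
    nch <- dim(v)[3]
    if (nch > 4) stop("read_raster: more than 4 channels", call. = FALSE)
    v <- if (nch >= 3)
      0.299 * v[, , 1] + 0.587 * v[, , 2] + 0.114 * v[, , 3]
    else v[, , 1]
  }
  if (kind == "mask") {
    lv <- round(v * 255)
    return(label_mask(lv, px,
                      class_names = if (!is.null(meta$class_names))
                        unlist(meta$class_names) else NULL))
  }
  if (kind == "histology") return(histology_image(pmin(pmax(v, 0), 1), px))
  ion_image(v, px,
            mz_center = if (!is.null(meta$mz_center)) meta$mz_center
              else NA_real_,
            mz_tolerance = if (!is.null(meta$mz_tolerance)) meta$mz_tolerance
              else NA_real_)
}
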