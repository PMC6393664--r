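#' Spectral dataset
#'
#' Per-pixel mass spectra on a rectangular acquisition grid. Grid
#' convention: 0-based row-major `(row, col)` coordinates; the pixel centre
#' sits at `(r + 0.5, c + 0.5) * pixel_size_um` in physical coordinates.
#'
#' @param positions Integer matrix `n x 2` of 0-based `(row, col)` grid
#'   coordinates; must be unique and within `grid_dim`.
#' @param mz List of numeric m/z vectors (Da), one per pixel.
#' @param intensity List of numeric intensity vectors (counts >= 0), one per
#'   pixel, each the length of its m/z vector.
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @param mz_range Numeric `(min, max)` in Da; defaults to the observed
#'   range over all pixels.
#' @param grid_dim Integer `(rows, cols)`; defaults to the bounding box of
#'   the positions.
#' @param mode `"continuous"` (shared m/z axis) or `"processed"`
#'   (per-pixel peak lists).
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(positions, mz, intensity, pixel_size_um,
                             mz_range = NULL, grid_dim = NULL,
                             mode = c("processed", "continuous")) {
  mode <- match.arg(mode)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "integer"
  n <- nrow(positions)
  if (length(mz) != n || length(intensity) != n)
    stop("spectral_dataset: positions, mz and intensity must have one entry ",
         "per pixel", call. = FALSE)
  if (anyDuplicated(positions) > 0)
    stop("spectral_dataset: duplicate pixel coordinate", call. = FALSE)
  if (any(positions < 0))
    stop("spectral_dataset: positions are 0-based and must be >= 0",
         call. = FALSE)
  if (is.null(grid_dim))
    grid_dim <- c(max(positions[, 1]) + 1L, max(positions[, 2]) + 1L)
  grid_dim <- as.integer(grid_dim)
  if (any(positions[, 1] >= grid_dim[1]) || any(positions[, 2] >= grid_dim[2]))
    stop("spectral_dataset: position outside the declared grid", call. = FALSE)
  for (i in seq_len(n)) {
    if (length(mz[[i]]) != length(intensity[[i]]))
      stop("spectral_dataset: m/z and intensity lengths differ at pixel ", i,
           call. = FALSE)
    if (any(intensity[[i]] < 0))
      stop("spectral_dataset: negative intensity at pixel ", i, call. = FALSE)
  }
  all_mz <- unlist(mz)
  if (is.null(mz_range))
    mz_range <- if (length(all_mz)) range(all_mz) else c(0, Inf)
  if (length(all_mz) && (any(all_mz < mz_range[1]) || any(all_mz > mz_range[2])))
    stop("spectral_dataset: m/z value outside mz_range", call. = FALSE)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("spectral_dataset: pixel_size_um must be > 0", call. = FALSE)
  structure(
    list(positions = positions, mz = mz, intensity = intensity,
         pixel_size_um = as.numeric(pixel_size_um),
         mz_range = as.numeric(mz_range), grid_dim = grid_dim, mode = mode),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "spectral_dataset (%s): %d pixels on %d x %d grid at %g um, m/z %g-%g Da\n",
    x$mode, nrow(x$positions), x$grid_dim[1], x$grid_dim[2],
    x$pixel_size_um, x$mz_range[1], x$mz_range[2]))
  invisible(x)
}

imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(xml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

#' Write a spectral dataset as imzML
#'
#' Writes the XML part (`.imzML`) and the binary data part (`.ibd`):
#' m/z values as 64-bit floats, intensities as 32-bit floats, external
#' offsets/lengths declared per spectrum. In continuous mode the shared m/z
#' axis is stored once and referenced by every spectrum.
#'
#' @param ds A [spectral_dataset()].
#' @param path Output path (with or without the `.imzML` extension).
#' @return The `.imzML` path, invisibly.
#' @export
write_imzml <- function(ds, path) {
  p <- imzml_paths(path)
  n <- nrow(ds$positions)
  continuous <- ds$mode == "continuous"

  ibd <- file(p$ibd, "wb")
  on.exit(close(ibd))
  uuid <- as.raw(c(0x70, 0x62, 0x73, 0x72, 0x2d, 0x69, 0x62, 0x64,
                   0x00, 0x01, 0x02, 0x03, 0x04, 0x05, 0x06, 0x07))
  writeBin(uuid, ibd)
  offset <- 16

  mz_off <- integer(n); mz_len <- integer(n)
  int_off <- integer(n); int_len <- integer(n)
  if (continuous) {
    axis <- if (n > 0) ds$mz[[1]] else numeric(0)
    writeBin(as.double(axis), ibd, size = 8, endian = "little")
    mz_off[] <- offset; mz_len[] <- length(axis)
    offset <- offset + 8 * length(axis)
  }
  for (i in seq_len(n)) {
    if (!continuous) {
      writeBin(as.double(ds$mz[[i]]), ibd, size = 8, endian = "little")
      mz_off[i] <- offset; mz_len[i] <- length(ds$mz[[i]])
      offset <- offset + 8 * mz_len[i]
    }
    writeBin(as.double(ds$intensity[[i]]), ibd, size = 4, endian = "little")
    int_off[i] <- offset; int_len[i] <- length(ds$intensity[[i]])
    offset <- offset + 4 * int_len[i]
  }

  cv <- function(ref, acc, name, value = NULL) {
    if (is.null(value))
      sprintf('<cvParam cvRef="%s" accession="%s" name="%s"/>', ref, acc, name)
    else
      sprintf('<cvParam cvRef="%s" accession="%s" name="%s" value="%s"/>',
              ref, acc, name, value)
  }
  mode_cv <- if (continuous) cv("IMS", "IMS:1000030", "continuous")
             else cv("IMS", "IMS:1000031", "processed")

  spectra <- character(n)
  for (i in seq_len(n)) {
    spectra[i] <- paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, mz_len[i]),
      '<scanList count="1"><scan>',
      # imzML positions are 1-based; x = column, y = row
      cv("IMS", "IMS:1000050", "position x", ds$positions[i, 2] + 1L),
      cv("IMS", "IMS:1000051", "position y", ds$positions[i, 1] + 1L),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cv("IMS", "IMS:1000103", "external array length", mz_len[i]),
      cv("IMS", "IMS:1000104", "external encoded length", 8L * mz_len[i]),
      cv("IMS", "IMS:1000102", "external offset", mz_off[i]),
      "<binary/></binaryDataArray>",
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cv("IMS", "IMS:1000103", "external array length", int_len[i]),
      cv("IMS", "IMS:1000104", "external encoded length", 4L * int_len[i]),
      cv("IMS", "IMS:1000102", "external offset", int_off[i]),
      "<binary/></binaryDataArray>",
      "</binaryDataArrayList></spectrum>")
  }

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    "</cvList>",
    "<fileDescription><fileContent>",
    mode_cv,
    cv("IMS", "IMS:1000080", "universally unique identifier",
       "{70627372-6962-6400-0102-030405060707}"),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS", "MS:1000514", "m/z array"),
    cv("MS", "MS:1000523", "64-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    cv("MS", "MS:1000515", "intensity array"),
    cv("MS", "MS:1000521", "32-bit float"),
    cv("MS", "MS:1000576", "no compression"),
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    '<softwareList count="1"><software id="pbsr" version="0.1.0">',
    cv("MS", "MS:1000799", "custom unreleased software tool", "pbsr"),
    "</software></softwareList>",
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    cv("IMS", "IMS:1000042", "max count of pixels x", ds$grid_dim[2]),
    cv("IMS", "IMS:1000043", "max count of pixels y", ds$grid_dim[1]),
    cv("IMS", "IMS:1000046", "pixel size x", ds$pixel_size_um),
    cv("IMS", "IMS:1000047", "pixel size y", ds$pixel_size_um),
    "</scanSettings></scanSettingsList>",
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1">',
    cv("MS", "MS:1000031", "instrument model"),
    "</instrumentConfiguration></instrumentConfigurationList>",
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="pbsr">',
    cv("MS", "MS:1000544", "Conversion to mzML"),
    "</processingMethod></dataProcessing></dataProcessingList>",
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1"><spectrumList count="%d" defaultDataProcessingRef="dp1">', n),
    paste(spectra, collapse = ""),
    "</spectrumList></run></mzML>")
  writeLines(xml, p$xml)
  invisible(p$xml)
}

xml_cv_value <- function(node, accession) {
  v <- xml2::xml_attr(
    xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']",
                                       accession)), "value")
  v
}

#' Read an imzML dataset
#'
#' Parses the XML part and reads the external binary arrays from the `.ibd`
#' file. Both continuous and processed mode are supported; no global m/z
#' axis is constructed in processed mode (extraction bins on the fly, so
#' memory stays proportional to the peaks actually touched).
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit next to it).
#' @param pixel_size_um Override/fallback pixel size; required if the file
#'   does not declare one.
#' @return A [spectral_dataset()].
#' @export
read_imzml <- function(path, pixel_size_um = NULL) {
  p <- imzml_paths(path)
  if (!file.exists(p$xml)) stop("no such file: ", p$xml, call. = FALSE)
  if (!file.exists(p$ibd))
    stop("missing binary data file: ", p$ibd, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(p$xml), error = function(e)
    stop("malformed imzML in ", p$xml, ": ", conditionMessage(e),
         call. = FALSE))
  xml2::xml_ns_strip(doc)

  fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
  continuous <- !is.na(xml2::xml_find_first(
    fc, ".//cvParam[@accession='IMS:1000030']"))
  processed <- !is.na(xml2::xml_find_first(
    fc, ".//cvParam[@accession='IMS:1000031']"))
  if (!continuous && !processed)
    stop("malformed imzML: fileContent declares neither continuous ",
         "(IMS:1000030) nor processed (IMS:1000031) mode", call. = FALSE)

  ss <- xml2::xml_find_first(doc, ".//scanSettings")
  px <- if (!is.na(ss)) suppressWarnings(as.numeric(
    xml_cv_value(ss, "IMS:1000046"))) else NA_real_
  if (is.na(px) || !length(px)) px <- NA_real_
  if (is.na(px)) {
    if (is.null(pixel_size_um))
      stop("imzML declares no pixel size (IMS:1000046); pass pixel_size_um",
           call. = FALSE)
    px <- pixel_size_um
  }
  nx <- suppressWarnings(as.integer(xml_cv_value(ss, "IMS:1000042")))
  ny <- suppressWarnings(as.integer(xml_cv_value(ss, "IMS:1000043")))

  # referenceable param groups: data type per array
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  gsize <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    is64 <- !is.na(xml2::xml_find_first(
      g, ".//cvParam[@accession='MS:1000523']"))
    is32 <- !is.na(xml2::xml_find_first(
      g, ".//cvParam[@accession='MS:1000521']"))
    is_mz <- !is.na(xml2::xml_find_first(
      g, ".//cvParam[@accession='MS:1000514']"))
    gsize[[id]] <- list(bytes = if (is64) 8L else if (is32) 4L else 8L,
                        is_mz = is_mz)
  }

  ibd <- file(p$ibd, "rb")
  on.exit(close(ibd))

  specs <- xml2::xml_find_all(doc, ".//spectrum")
  n <- length(specs)
  positions <- matrix(0L, n, 2)
  mz <- vector("list", n)
  intensity <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    x <- suppressWarnings(as.integer(xml_cv_value(sp, "IMS:1000050")))
    y <- suppressWarnings(as.integer(xml_cv_value(sp, "IMS:1000051")))
    if (is.na(x) || is.na(y))
      stop("malformed imzML: spectrum ", i,
           " lacks position cvParams (IMS:1000050/51)", call. = FALSE)
    positions[i, ] <- c(y - 1L, x - 1L)
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, ".//referenceableParamGroupRef"), "ref")
      g <- gsize[[ref]]
      if (is.null(g))
        stop("malformed imzML: unknown referenceableParamGroupRef '", ref,
             "'", call. = FALSE)
      len <- as.integer(xml_cv_value(bda, "IMS:1000103"))
      off <- as.numeric(xml_cv_value(bda, "IMS:1000102"))
      if (is.na(len) || is.na(off))
        stop("malformed imzML: binaryDataArray without external ",
             "offset/length (IMS:1000102/03)", call. = FALSE)
      seek(ibd, where = off, origin = "start")
      vals <- readBin(ibd, what = "double", n = len, size = g$bytes,
                      endian = "little")
      if (g$is_mz) mz[[i]] <- vals else intensity[[i]] <- vals
    }
  }
  grid_dim <- if (!is.na(ny) && !is.na(nx)) c(ny, nx) else NULL
  spectral_dataset(positions, mz, intensity, px, grid_dim = grid_dim,
                   mode = if (continuous) "continuous" else "processed")
}

#' Total-ion-count normalization
#'
#' Divides each pixel's intensities by that pixel's total intensity sum, the
#' standard per-pixel normalization for MSI. Pixels with zero total are left
#' all-zero (the grid stays rectangular) and flagged in the attached report.
#'
#' @param ds A [spectral_dataset()].
#' @return The normalized dataset, with attribute `"tic_report"`: a list
#'   with `n_zero_tic` and `zero_tic_pixels` (indices into the pixel list).
#'   A warning is emitted when zero-TIC pixels exist.
#' @export
tic_normalize <- function(ds) {
  tics <- vapply(ds$intensity, sum, numeric(1))
  zero <- which(tics == 0)
  out <- ds
  for (i in seq_along(ds$intensity))
    if (tics[i] > 0) out$intensity[[i]] <- ds$intensity[[i]] / tics[i]
  if (length(zero) > 0)
    warning(length(zero), " pixel(s) with zero total ion count left as zero",
            call. = FALSE)
  attr(out, "tic_report") <- list(n_zero_tic = length(zero),
                                  zero_tic_pixels = zero)
  out
}

#' Extract an ion image for one m/z window
#'
#' Per pixel, sums all intensities with `|mz - mz_center| <= mz_tolerance`;
#' grid positions without a spectrum are 0.
#'
#' @param ds A [spectral_dataset()].
#' @param mz_center Window centre in Da.
#' @param mz_tolerance Window half-width in Da (> 0).
#' @return An [ion_image()] on the acquisition grid.
#' @export
extract_ion_image <- function(ds, mz_center, mz_tolerance) {
  if (!is.numeric(mz_tolerance) || mz_tolerance <= 0)
    stop("mz_tolerance must be > 0", call. = FALSE)
  if (mz_center + mz_tolerance < ds$mz_range[1] ||
      mz_center - mz_tolerance > ds$mz_range[2])
    stop(sprintf(
      "m/z window %.4f +/- %.4f lies outside the dataset range %.4f-%.4f",
      mz_center, mz_tolerance, ds$mz_range[1], ds$mz_range[2]),
      call. = FALSE)
  vals <- matrix(0, ds$grid_dim[1], ds$grid_dim[2])
  for (i in seq_len(nrow(ds$positions))) {
    sel <- abs(ds$mz[[i]] - mz_center) <= mz_tolerance
    vals[ds$positions[i, 1] + 1L, ds$positions[i, 2] + 1L] <-
      sum(ds$intensity[[i]][sel])
  }
  ion_image(vals, ds$pixel_size_um, mz_center, mz_tolerance)
}
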