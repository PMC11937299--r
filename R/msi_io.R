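#' Construct a single profile-mode spectrum
#'
#' @param mz strictly increasing m/z axis (length >= 2).
#' @param intensity nonnegative intensities, same length as `mz`.
#' @return A `msi_spectrum` (list with `mz`, `intensity`).
#' @export
msi_spectrum <- function(mz, intensity) {
  validate_spectrum(mz, intensity)
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "msi_spectrum")
}

validate_spectrum <- function(mz, intensity, what = "spectrum") {
  if (length(mz) < 2) stop(what, ": m/z axis must have length >= 2")
  if (length(mz) != length(intensity))
    stop(what, ": m/z and intensity lengths differ")
  if (any(diff(mz) <= 0)) stop(what, ": m/z axis is not strictly increasing")
  if (any(intensity < 0)) stop(what, ": negative intensities")
  invisible(TRUE)
}

#' Construct an MSI raster
#'
#' A raster is the pixel grid of one imaging run: per-pixel profile spectra
#' plus acquisition metadata. Pixel coordinates are 0-based, `x` rightward
#' and `y` downward. Two storage modes exist: *continuous* (one shared m/z
#' axis, intensities as a pixels-by-samples matrix) and *processed*
#' (per-pixel m/z axes, a list of spectra). The synthetic generator and the
#' fast peak-picking path use continuous mode.
#'
#' @param mz shared m/z axis (continuous mode) or `NULL`.
#' @param intensity pixels-by-samples matrix (continuous) or `NULL`.
#' @param spectra list of `msi_spectrum` (processed mode) or `NULL`.
#' @param coords data frame with 0-based integer columns `x`, `y`, one row
#'   per pixel, aligned with `intensity` rows / `spectra` elements.
#' @param pixel_um raster step size in micrometers (default 125).
#' @param metadata free-form provenance list.
#' @return A `msi_raster` object.
#' @export
msi_raster <- function(mz = NULL, intensity = NULL, spectra = NULL, coords,
                       pixel_um = 125, metadata = list()) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("x", "y") %in% names(coords)))
  if (nrow(coords) == 0) stop("no pixels")
  if (any(coords$x < 0) || any(coords$y < 0) ||
      any(coords$x != floor(coords$x)) || any(coords$y != floor(coords$y)))
    stop("pixel coordinates must be 0-based integers")
  if (anyDuplicated(coords[c("x", "y")])) stop("duplicate pixel coordinates")
  if (!is.null(spectra)) {
    if (length(spectra) != nrow(coords))
      stop("number of spectra does not match number of pixels")
    mode <- "processed"
  } else {
    stopifnot(is.matrix(intensity), nrow(intensity) == nrow(coords),
              length(mz) == ncol(intensity))
    validate_spectrum(mz, rep(0, length(mz)), "raster m/z axis")
    if (any(intensity < 0)) stop("negative intensities")
    mode <- "continuous"
  }
  structure(list(mode = mode, mz = mz, intensity = intensity,
                 spectra = spectra, coords = coords, pixel_um = pixel_um,
                 metadata = metadata),
            class = "msi_raster")
}

#' @export
print.msi_raster <- function(x, ...) {
  rng <- if (x$mode == "continuous") range(x$mz) else
    range(unlist(lapply(x$spectra, function(s) range(s$mz))))
  cat(sprintf("<msi_raster> %d pixels, %s mode, m/z %.1f-%.1f, %g um step\n",
              nrow(x$coords), x$mode, rng[1], rng[2], x$pixel_um))
  invisible(x)
}

n_pixels <- function(raster) nrow(raster$coords)

#' Extract one pixel's spectrum from a raster
#'
#' @param raster a `msi_raster`.
#' @param i pixel index (row of `raster$coords`).
#' @return A `msi_spectrum`.
#' @export
pixel_spectrum <- function(raster, i) {
  if (raster$mode == "continuous")
    msi_spectrum(raster$mz, raster$intensity[i, ])
  else raster$spectra[[i]]
}

#' Total ion current image
#'
#' Sums each pixel's intensities and arranges them on the raster's bounding
#' box; positions never scanned are 0.
#'
#' @param raster a `msi_raster`.
#' @return Numeric matrix indexed `[y + 1, x + 1]`.
#' @export
tic_image <- function(raster) {
  tic <- if (raster$mode == "continuous") rowSums(raster$intensity) else
    vapply(raster$spectra, function(s) sum(s$intensity), 0)
  nx <- max(raster$coords$x) + 1L
  ny <- max(raster$coords$y) + 1L
  img <- matrix(0, nrow = ny, ncol = nx)
  img[cbind(raster$coords$y + 1L, raster$coords$x + 1L)] <- tic
  img
}

## ---------------------------------------------------------------------------
## Internal container: a directory holding
##   meta.json       format version, mode, pixel_um, counts, metadata
##   coords.tsv      tab-delimited 0-based x, y (one row per pixel)
##   mz.bin          IEEE-754 little-endian doubles (shared axis, or all
##                   per-pixel axes concatenated in pixel order)
##   intensity.bin   doubles, pixel-major (pixel 1's samples, then pixel 2's)
##   lengths.tsv     processed mode only: samples per pixel
## The layout is plain enough to read from any language.

#' Write / read a raster
#'
#' `format = "container"` is the package's documented directory layout with a
#' JSON metadata file and little-endian binary arrays (lossless round trip).
#' `format = "imzML"` writes a continuous-mode imzML/ibd pair and reads both
#' continuous- and processed-mode files; imzML's 1-based pixel coordinates
#' are converted to this package's 0-based convention on import.
#'
#' @param raster a `msi_raster`.
#' @param path directory (container) or `.imzML` file path.
#' @param format `"container"` or `"imzML"`.
#' @return `read_raster` returns a `msi_raster`.
#' @export
write_raster <- function(raster, path, format = c("container", "imzML")) {
  format <- match.arg(format)
  if (format == "imzML") return(write_imzml(raster, path))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "lignims-raster", version = 1L, mode = raster$mode,
               pixel_um = raster$pixel_um, n_pixels = n_pixels(raster),
               metadata = raster$metadata)
  if (raster$mode == "continuous") meta$n_mz <- length(raster$mz)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(raster$coords[c("x", "y")], file.path(path, "coords.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  wbin <- function(x, f) {
    con <- file(file.path(path, f), "wb")
    on.exit(close(con))
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  }
  if (raster$mode == "continuous") {
    wbin(raster$mz, "mz.bin")
    wbin(as.vector(t(raster$intensity)), "intensity.bin")
  } else {
    lens <- vapply(raster$spectra, function(s) length(s$mz), 0L)
    write.table(data.frame(length = lens), file.path(path, "lengths.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    wbin(unlist(lapply(raster$spectra, `[[`, "mz")), "mz.bin")
    wbin(unlist(lapply(raster$spectra, `[[`, "intensity")), "intensity.bin")
  }
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path, format = c("container", "imzML")) {
  format <- match.arg(format)
  if (format == "imzML") return(read_imzml(path))
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  if (!identical(meta$format, "lignims-raster"))
    stop("not a lignims raster container: ", path)
  coords <- read.delim(file.path(path, "coords.tsv"))
  if (nrow(coords) == 0) stop("no pixels")
  rbin <- function(f, n) {
    con <- file(file.path(path, f), "rb")
    on.exit(close(con))
    readBin(con, "numeric", n = n, size = 8, endian = "little")
  }
  if (meta$mode == "continuous") {
    mz <- rbin("mz.bin", meta$n_mz)
    intens <- matrix(rbin("intensity.bin", meta$n_mz * meta$n_pixels),
                     nrow = meta$n_pixels, ncol = meta$n_mz, byrow = TRUE)
    msi_raster(mz = mz, intensity = intens, coords = coords,
               pixel_um = meta$pixel_um, metadata = meta$metadata)
  } else {
    lens <- read.delim(file.path(path, "lengths.tsv"))$length
    mz <- rbin("mz.bin", sum(lens))
    it <- rbin("intensity.bin", sum(lens))
    ends <- cumsum(lens); starts <- ends - lens + 1
    spectra <- lapply(seq_along(lens), function(i)
      msi_spectrum(mz[starts[i]:ends[i]], it[starts[i]:ends[i]]))
    msi_raster(spectra = spectra, coords = coords,
               pixel_um = meta$pixel_um, metadata = meta$metadata)
  }
}

## ---------------------------------------------------------------------------
## Minimal imzML support (64-bit float arrays, no compression). The .ibd
## companion holds a 16-byte UUID followed by the external arrays referenced
## by byte offset from the XML.

IMZML_UUID <- as.raw(c(0x4c, 0x69, 0x67, 0x4e, 0x49, 0x4d, 0x53, 0x2d,
                       0x72, 0x61, 0x73, 0x74, 0x65, 0x72, 0x30, 0x31))

write_imzml <- function(raster, path) {
  if (raster$mode != "continuous")
    stop("imzML export is implemented for continuous-mode rasters")
  if (!grepl("\\.imzML$", path)) path <- paste0(path, ".imzML")
  ibd_path <- sub("\\.imzML$", ".ibd", path)
  npx <- n_pixels(raster); nmz <- length(raster$mz)
  con <- file(ibd_path, "wb")
  writeBin(IMZML_UUID, con)
  writeBin(as.numeric(raster$mz), con, size = 8, endian = "little")
  for (i in seq_len(npx))
    writeBin(as.numeric(raster$intensity[i, ]), con, size = 8, endian = "little")
  close(con)
  mz_off <- 16
  int_off <- 16 + 8 * nmz + 8 * nmz * (seq_len(npx) - 1)
  spec <- vapply(seq_len(npx), function(i) {
    sprintf(paste0(
      '   <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">\n',
      '    <scanList count="1">\n',
      '     <scan>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
      '     </scan>\n',
      '    </scanList>\n',
      '    <binaryDataArrayList count="2">\n',
      '     <binaryDataArray encodedLength="0">\n',
      '      <referenceableParamGroupRef ref="mzArray"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
      '      <binary/>\n',
      '     </binaryDataArray>\n',
      '     <binaryDataArray encodedLength="0">\n',
      '      <referenceableParamGroupRef ref="intensityArray"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
      '      <binary/>\n',
      '     </binaryDataArray>\n',
      '    </binaryDataArrayList>\n',
      '   </spectrum>'),
      i, i - 1L, nmz,
      raster$coords$x[i] + 1L, raster$coords$y[i] + 1L,
      nmz, mz_off, nmz, int_off[i])
  }, "")
  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    ' <fileDescription>\n',
    '  <fileContent>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>\n',
    '  </fileContent>\n',
    ' </fileDescription>\n',
    ' <referenceableParamGroupList count="2">\n',
    '  <referenceableParamGroup id="mzArray">\n',
    '   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '  </referenceableParamGroup>\n',
    '  <referenceableParamGroup id="intensityArray">\n',
    '   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>\n',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '  </referenceableParamGroup>\n',
    ' </referenceableParamGroupList>\n',
    ' <run id="run0">\n',
    sprintf('  <spectrumList count="%d">\n', npx),
    paste(spec, collapse = "\n"), "\n",
    '  </spectrumList>\n',
    ' </run>\n',
    '</mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

read_imzml <- function(path) {
  ibd_path <- sub("\\.imzML$", ".ibd", path)
  if (!file.exists(path)) stop("imzML file not found: ", path)
  if (!file.exists(ibd_path)) stop("ibd companion not found: ", ibd_path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mode_node <- xml2::xml_find_first(
    doc, ".//fileContent/cvParam[@accession='IMS:1000030' or @accession='IMS:1000031']")
  if (inherits(mode_node, "xml_missing"))
    stop("imzML parse error: missing continuous/processed mode cvParam in fileContent")
  continuous <- xml2::xml_attr(mode_node, "accession") == "IMS:1000030"
  specs <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (length(specs) == 0) stop("no pixels")
  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd))
  read_array <- function(offset, n) {
    seek(ibd, where = offset)
    readBin(ibd, "numeric", n = n, size = 8, endian = "little")
  }
  arr_info <- function(sp, ref, id) {
    node <- xml2::xml_find_first(
      sp, sprintf(".//binaryDataArray[referenceableParamGroupRef/@ref='%s']", ref))
    if (inherits(node, "xml_missing"))
      stop("imzML parse error in spectrum '", id, "': missing ", ref)
    g <- function(acc) as.numeric(xml2::xml_attr(
      xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", acc)), "value"))
    list(offset = g("IMS:1000102"), length = g("IMS:1000103"))
  }
  n <- length(specs)
  xs <- ys <- integer(n)
  mz_shared <- NULL
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    id <- xml2::xml_attr(sp, "id")
    pos <- function(acc) as.integer(xml2::xml_attr(
      xml2::xml_find_first(sp, sprintf(".//cvParam[@accession='%s']", acc)), "value"))
    xs[i] <- pos("IMS:1000050"); ys[i] <- pos("IMS:1000051")
    if (is.na(xs[i]) || is.na(ys[i]))
      stop("imzML parse error in spectrum '", id, "': missing pixel position")
    mzi <- arr_info(sp, "mzArray", id)
    iti <- arr_info(sp, "intensityArray", id)
    mzv <- if (continuous && !is.null(mz_shared)) mz_shared else
      read_array(mzi$offset, mzi$length)
    if (continuous && is.null(mz_shared)) mz_shared <- mzv
    itv <- read_array(iti$offset, iti$length)
    if (any(diff(mzv) <= 0))
      stop("imzML parse error in spectrum '", id,
           "': m/z axis is not strictly increasing")
    spectra[[i]] <- msi_spectrum(mzv, itv)
  }
  coords <- data.frame(x = xs - 1L, y = ys - 1L)  # imzML is 1-based
  if (continuous) {
    intens <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
    msi_raster(mz = mz_shared, intensity = intens, coords = coords,
               metadata = list(source = path))
  } else {
    msi_raster(spectra = spectra, coords = coords,
               metadata = list(source = path))
  }
}
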