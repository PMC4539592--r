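# TIFF carriers.
#
# Reading goes through tiff::readTIFF, which handles integer (as recorded
# values via as.is) and IEEE-float sample formats, multi-page files and NaN.
# Writing float data is done by a minimal built-in writer: the installed
# writers only store 32-bit samples as [0,1]-scaled unsigned integers, which
# cannot carry NaN sentinels or values outside [0,1], and GP maps need both
# (GP lives in [-1,1], excluded pixels are NaN, and the round-trip must be
# bit-exact). The writer emits plain uncompressed little-endian baseline
# TIFF, single strip per page, SampleFormat = IEEE float.

# Write one matrix (single page) or a list of equally-sized matrices
# (multi-page) as an uncompressed 32-bit float grayscale TIFF.
write_float_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1))))
  dims <- vapply(pages, dim, integer(2))
  if (length(pages) > 1L && any(dims != dims[, 1L]))
    stop("all pages must have identical dimensions")
  h <- dims[1L, 1L]; w <- dims[2L, 1L]
  nbytes <- 4L * h * w
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L              # entry count + entries + next-IFD
  # layout: 8-byte header, then per page [IFD][strip data]
  ifd_off <- 8L + (seq_along(pages) - 1L) * (ifd_size + nbytes)
  data_off <- ifd_off + ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  wr16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # header: little-endian magic, version 42, offset of first IFD
  writeBin(charToRaw("II"), con); wr16(42L); wr32(ifd_off[1L])
  tag <- function(id, type, count, value) { wr16(id); wr16(type); wr32(count)
    if (type == 3L) { wr16(value); wr16(0L) } else wr32(value) }   # 3=SHORT, 4=LONG
  for (i in seq_along(pages)) {
    wr16(n_tags)
    tag(256L, 4L, 1L, w)                 # ImageWidth
    tag(257L, 4L, 1L, h)                 # ImageLength
    tag(258L, 3L, 1L, 32L)               # BitsPerSample
    tag(259L, 3L, 1L, 1L)                # Compression: none
    tag(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
    tag(273L, 4L, 1L, data_off[i])       # StripOffsets
    tag(277L, 3L, 1L, 1L)                # SamplesPerPixel
    tag(278L, 4L, 1L, h)                 # RowsPerStrip: one strip
    tag(279L, 4L, 1L, nbytes)            # StripByteCounts
    tag(339L, 3L, 1L, 3L)                # SampleFormat: IEEE float
    wr32(if (i < length(pages)) ifd_off[i + 1L] else 0L)
    # strip data, row-major
    writeBin(as.numeric(t(pages[[i]])), con, size = 4L, endian = "little")
  }
  invisible(path)
}

# Read all pages of a TIFF as a list of matrices carrying recorded values:
# integer types as stored (no [0,1] rescaling), float types verbatim.
read_tiff_pages <- function(path, info = FALSE) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = info),
    error = function(e) {
      if (grepl("as.is", conditionMessage(e), fixed = TRUE))
        tiff::readTIFF(path, all = TRUE, info = info)   # float samples
      else stop(e)
    })
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) > 2L)
      stop("only single-sample (grayscale) spectral TIFFs are supported")
    storage.mode(p) <- "double"
    p
  })
}

#' Read a spectral image stack from a multi-page TIFF
#'
#' Each TIFF page is one spectral detection channel, ordered by ascending
#' wavelength. Integer pixel types are promoted to numeric without
#' rescaling; 32-bit float pages are read verbatim. Small negative values
#' (detector offsets) are clipped to zero with a warning, since the model
#' space is nonnegative emission.
#'
#' The wavelength axis is taken from `axis` when supplied. With
#' `axis = "from-metadata"` the reader looks for OME-XML channel metadata
#' (`EmissionWavelength` attributes on a uniform grid) in the ImageDescription
#' tag; an explicit axis always wins, and a page-count mismatch against the
#' declared axis is an error, never silently resolved.
#'
#' @param path Path to a multi-page TIFF / OME-TIFF file.
#' @param axis A [wavelength_axis()], or `"from-metadata"` to read the axis
#'   from OME metadata.
#' @return A [spectral_stack()].
#' @export
read_spectral_stack <- function(path, axis = "from-metadata") {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  from_meta <- identical(axis, "from-metadata")
  if (!from_meta && !is_wavelength_axis(axis))
    stop("'axis' must be a wavelength_axis or \"from-metadata\"")
  pages <- read_tiff_pages(path, info = from_meta)
  if (from_meta)
    axis <- axis_from_ome_description(attr(pages[[1L]], "description"), path)
  if (length(pages) != axis$n_channels)
    stop(sprintf("'%s' has %d pages but the wavelength axis declares %d channels",
                 path, length(pages), axis$n_channels))
  d <- dim(pages[[1L]])
  arr <- array(NA_real_, c(d[1L], d[2L], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  if (any(arr < 0)) {
    warning(sprintf("%d negative intensities clipped to 0 on load", sum(arr < 0)))
    arr[arr < 0] <- 0
  }
  spectral_stack(arr, axis, source = path)
}

# Build a wavelength_axis from an OME-XML ImageDescription, if possible.
axis_from_ome_description <- function(desc, path) {
  fail <- function(why)
    stop(sprintf(paste0("cannot read a wavelength axis from '%s' (%s); ",
                        "pass an explicit wavelength_axis(start_nm, width_nm, n_channels)"),
                 path, why))
  if (is.null(desc) || !nzchar(desc) || !grepl("<OME", desc, fixed = TRUE))
    fail("no OME-XML metadata")
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) fail("unparsable OME-XML")
  ch <- xml2::xml_find_all(doc, ".//*[local-name()='Channel']")
  em <- suppressWarnings(as.numeric(xml2::xml_attr(ch, "EmissionWavelength")))
  if (length(em) < 3L || anyNA(em)) fail("no per-channel EmissionWavelength")
  em <- sort(em)
  steps <- diff(em)
  if (max(steps) - min(steps) > 1e-6) fail("channel wavelengths are not on a uniform grid")
  width <- mean(steps)
  wavelength_axis(em[1L] - width / 2, width, length(em))
}

#' Write a spectral stack as a multi-page 32-bit float TIFF
#'
#' One page per channel, ascending wavelength. Values are stored at single
#' precision (the float TIFF sample format) and round-trip bit-exactly at
#' that precision through [read_spectral_stack()]; detector counts below
#' 2^24 are represented exactly.
#'
#' @param stack A [spectral_stack()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_spectral_stack <- function(stack, path) {
  stopifnot(is_spectral_stack(stack))
  pages <- lapply(seq_len(stack$axis$n_channels), function(k) stack$data[, , k])
  write_float_tiff(pages, path)
}
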