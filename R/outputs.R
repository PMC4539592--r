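#' Write the standard output set of a GP analysis
#'
#' Writes, into `out_dir`:
#' \describe{
#'   \item{`gp.tif`}{GP map as 32-bit float single-page TIFF; pixels outside
#'     the mask (or excluded by fit failure / R-squared filtering) are `NaN`
#'     — never 0, which is a legal GP value. Values are stored at single
#'     precision and re-read bit-exactly at that precision.}
#'   \item{`gp_lut.png`}{8-bit rendering of the GP map under a fixed
#'     diverging blue-to-red colormap spanning GP -1 (blue, disordered) to
#'     +1 (red, ordered); excluded pixels are black.}
#'   \item{`mask.tif`}{analysis mask as 8-bit TIFF (0 / 255).}
#'   \item{`r2.tif`}{per-pixel R-squared as float TIFF (fitting methods
#'     only).}
#'   \item{`gp_histogram.csv`}{histogram with columns `bin_left`,
#'     `bin_right`, `count`.}
#'   \item{`gp_summary.csv`}{`mean`, `sd`, `median`, `median_positive`,
#'     `median_negative`, `n_pixels`, `n_fit_failures`.}
#' }
#'
#' @param gpmap A [compute_gp_map()] result.
#' @param out_dir Output directory (created if missing).
#' @param bin_width Histogram bin width (default 0.02).
#' @return Named character vector of the files written, invisibly.
#' @export
write_gp_outputs <- function(gpmap, out_dir, bin_width = 0.02) {
  stopifnot(is_gp_map(gpmap))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  paths <- c(gp = file.path(out_dir, "gp.tif"),
             lut = file.path(out_dir, "gp_lut.png"),
             mask = file.path(out_dir, "mask.tif"),
             histogram = file.path(out_dir, "gp_histogram.csv"),
             summary = file.path(out_dir, "gp_summary.csv"))
  write_float_tiff(gpmap$gp, paths[["gp"]])
  png::writePNG(gp_lut_render(gpmap$gp), paths[["lut"]])
  tiff::writeTIFF(gpmap$mask$include * 1, paths[["mask"]],
                  bits.per.sample = 8L, compression = "none")
  if (!is.null(gpmap$r2)) {
    paths <- c(paths, r2 = file.path(out_dir, "r2.tif"))
    write_float_tiff(gpmap$r2, paths[["r2"]])
  }
  h <- gp_histogram(gpmap, bin_width)
  utils::write.csv(as.data.frame(h), paths[["histogram"]], row.names = FALSE)
  utils::write.csv(
    data.frame(mean = h$mean, sd = h$sd, median = h$median,
               median_positive = h$median_positive,
               median_negative = h$median_negative,
               n_pixels = h$n_pixels,
               n_fit_failures = gpmap$n_fit_failures),
    paths[["summary"]], row.names = FALSE)
  invisible(paths)
}

# RGB rendering of a GP matrix: fixed diverging blue-white-red map over
# [-1, 1] ("Blue-Red 3" HCL palette), excluded (NaN) pixels black.
gp_lut_render <- function(gp, n_colors = 256L) {
  pal <- grDevices::hcl.colors(n_colors, "Blue-Red 3")
  rgbm <- grDevices::col2rgb(pal) / 255
  idx <- pmax(1L, pmin(n_colors, 1L + floor((gp + 1) / 2 * n_colors)))
  out <- array(0, c(nrow(gp), ncol(gp), 3L))
  ok <- is.finite(gp)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[ok] <- rgbm[ch, idx[ok]]
    out[, , ch] <- plane
  }
  out
}

#' Read a GP map (or any float image) back from a float TIFF
#'
#' Convenience reader for the float TIFFs written by [write_gp_outputs()]
#' and [write_spectral_stack()]; returns the matrix with `NaN` preserved.
#'
#' @param path Path to a single-page float TIFF.
#' @return Numeric matrix.
#' @export
read_float_image <- function(path) {
  pages <- read_tiff_pages(path)
  if (length(pages) != 1L) stop("expected a single-page image")
  pages[[1L]]
}
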