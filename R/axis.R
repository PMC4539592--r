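#' Wavelength axis of a spectral detector
#'
#' Describes how the channels of a lambda-mode detector map to emission
#' wavelengths: `n_channels` contiguous windows of width `width_nm`, the
#' first starting (lower edge) at `start_nm`. Channel `k` (1-based) is
#' represented by its central wavelength
#' `start_nm + width_nm * (k - 1/2)`, the convention used when a spectral
#' stack slice is treated as the intensity at a single wavelength.
#'
#' The default axis of the package's examples, 32 channels of 8.9 nm from
#' 415 nm, covers 415--699.8 nm (last center 695.35 nm), the detection
#' range of a 32-channel GaAsP lambda detector.
#'
#' @param start_nm Lower edge of the first channel, in nm.
#' @param width_nm Channel width, in nm. Must be positive.
#' @param n_channels Number of channels; at least 3 (fitting a 3--4
#'   parameter line shape needs at least as many samples).
#' @return An object of class `wavelength_axis` with fields `start_nm`,
#'   `width_nm`, `n_channels` and the derived `centers_nm`.
#' @examples
#' ax <- wavelength_axis(415, 8.9, 32)
#' ax$centers_nm[1]   # 419.45
#' @export
wavelength_axis <- function(start_nm, width_nm, n_channels) {
  stopifnot(is.numeric(start_nm), length(start_nm) == 1L, is.finite(start_nm),
            is.numeric(width_nm), length(width_nm) == 1L, is.finite(width_nm),
            is.numeric(n_channels), length(n_channels) == 1L)
  if (width_nm <= 0)
    stop("'width_nm' must be positive")
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 3L)
    stop("'n_channels' must be an integer >= 3")
  structure(
    list(start_nm = as.numeric(start_nm),
         width_nm = as.numeric(width_nm),
         n_channels = n_channels,
         centers_nm = start_nm + width_nm * (seq_len(n_channels) - 0.5)),
    class = "wavelength_axis")
}

#' @export
print.wavelength_axis <- function(x, ...) {
  cat(sprintf("<wavelength_axis> %d channels of %.6g nm from %.6g nm (centers %.6g-%.6g nm)\n",
              x$n_channels, x$width_nm, x$start_nm,
              x$centers_nm[1L], x$centers_nm[x$n_channels]))
  invisible(x)
}

is_wavelength_axis <- function(x) inherits(x, "wavelength_axis")

#' Nearest detection channel for a wavelength
#'
#' Returns the index (1-based) of the channel whose center wavelength is
#' closest to `lambda_nm`. A wavelength exactly midway between two centers
#' resolves to the lower-wavelength channel; there is no physical reason to
#' prefer either, and the lower index makes the choice deterministic.
#'
#' @param axis A [wavelength_axis()].
#' @param lambda_nm Wavelength in nm. Must lie within one channel width of
#'   the covered centers, i.e. in `[centers[1] - width, centers[n] + width]`;
#'   anything further out has no sensible nearest channel and is an error.
#' @return Integer channel index.
#' @export
nearest_channel <- function(axis, lambda_nm) {
  stopifnot(is_wavelength_axis(axis), is.numeric(lambda_nm),
            length(lambda_nm) == 1L, is.finite(lambda_nm))
  ctr <- axis$centers_nm
  lo <- ctr[1L] - axis$width_nm
  hi <- ctr[axis$n_channels] + axis$width_nm
  if (lambda_nm < lo || lambda_nm > hi)
    stop(sprintf("wavelength %.6g nm is outside the detection axis [%.6g, %.6g] nm",
                 lambda_nm, lo, hi))
  d <- abs(ctr - lambda_nm)
  # ties (midway between two centers) resolve to the lower index; the
  # tolerance guards against last-ulp asymmetry in the subtraction
  which(d <= min(d) + 1e-9)[1L]
}
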