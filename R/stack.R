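#' Spectral image stack
#'
#' A lambda-mode acquisition: one 2-D intensity image per spectral detection
#' channel, stored as a `rows x cols x channels` array bound to the
#' [wavelength_axis()] that maps the channel index to an emission
#' wavelength. Intensities are in arbitrary detector units and must be
#' nonnegative (the model space is nonnegative emission).
#'
#' @param data Numeric 3-D array, `rows x cols x channels`.
#' @param axis A [wavelength_axis()]; `dim(data)[3]` must equal
#'   `axis$n_channels`.
#' @param source Free-text provenance (file path or `"synthetic"`).
#' @return An object of class `spectral_stack`.
#' @export
spectral_stack <- function(data, axis, source = "in-memory") {
  stopifnot(is.array(data), length(dim(data)) == 3L, is.numeric(data),
            is_wavelength_axis(axis), is.character(source), length(source) == 1L)
  if (dim(data)[3L] != axis$n_channels)
    stop(sprintf("stack has %d channel planes but the axis declares %d channels",
                 dim(data)[3L], axis$n_channels))
  if (anyNA(data) || any(!is.finite(data)))
    stop("stack intensities must be finite")
  if (any(data < 0))
    stop("stack intensities must be nonnegative")
  structure(list(data = data, axis = axis, source = source),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_stack> %d x %d pixels, %d channels (%s)\n",
              d[1L], d[2L], d[3L], x$source))
  print(x$axis)
  invisible(x)
}

is_spectral_stack <- function(x) inherits(x, "spectral_stack")

#' @export
dim.spectral_stack <- function(x) dim(x$data)

#' Per-channel detector sensitivity correction
#'
#' Multiplies every channel plane by a positive per-channel factor,
#' compensating differences in sensitivity between spectral detection
#' channels. Factory-normalized detectors need the identity correction
#' (all ones). A correction that is uniform across channels cancels in the
#' GP ratio and leaves every GP value unchanged.
#'
#' @param stack A [spectral_stack()].
#' @param factors Numeric vector of positive multipliers, one per channel.
#' @return A corrected `spectral_stack`.
#' @export
apply_sensitivity_correction <- function(stack, factors) {
  stopifnot(is_spectral_stack(stack), is.numeric(factors))
  n <- stack$axis$n_channels
  if (length(factors) != n)
    stop(sprintf("correction has %d factors but the stack has %d channels",
                 length(factors), n))
  if (anyNA(factors) || any(!is.finite(factors) | factors <= 0))
    stop("sensitivity correction factors must be finite and > 0")
  d <- stack$data
  for (k in seq_len(n)) d[, , k] <- d[, , k] * factors[k]
  spectral_stack(d, stack$axis, stack$source)
}

#' Extract the spectrum of one pixel
#'
#' @param stack A [spectral_stack()].
#' @param row,col Pixel coordinates (1-based).
#' @return Numeric vector of length `n_channels`.
#' @export
pixel_spectrum <- function(stack, row, col) {
  stopifnot(is_spectral_stack(stack))
  stack$data[row, col, ]
}
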