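#' Z-projection of a spectral stack
#'
#' Pixelwise sum of all channel planes, i.e. the total detected fluorescence
#' per pixel. The projection is what the analysis mask is thresholded on:
#' membrane pixels carry signal in many channels and project high, background
#' pixels project low.
#'
#' @param stack A [spectral_stack()].
#' @return Numeric matrix, `rows x cols`.
#' @export
z_project <- function(stack) {
  stopifnot(is_spectral_stack(stack))
  rowSums(stack$data, dims = 2L)
}

#' Rescale an image linearly onto the 8-bit 0--255 range
#'
#' Linear min-to-0, max-to-255 mapping, rounded to the nearest integer, so a
#' user-chosen mask threshold is always interpreted on the same 0--255 scale
#' regardless of detector bit depth. A constant image maps to all zeros
#' (fail-safe: nothing passes a positive threshold).
#'
#' @param image Numeric matrix with finite values.
#' @return Integer-valued matrix on 0--255.
#' @export
to_8bit_scale <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (anyNA(image) || any(!is.finite(image))) stop("image must be finite")
  rng <- range(image)
  if (rng[2L] == rng[1L]) return(array(0, dim(image)))
  round((image - rng[1L]) / (rng[2L] - rng[1L]) * 255)
}

#' Fluorescence-positive analysis mask
#'
#' Thresholds the 8-bit Z-projection: a pixel is analyzed when its projected
#' value is strictly greater than `threshold`. Everything else is "dark
#' area" and is used for background estimation.
#'
#' @param projection_8bit Matrix on the 0--255 scale (see [to_8bit_scale()]).
#' @param threshold Integer in 0--255 (default 15).
#' @return An object of class `gp_mask`: list with logical matrix `include`
#'   and the `threshold` used.
#' @export
compute_mask <- function(projection_8bit, threshold = 15L) {
  stopifnot(is.matrix(projection_8bit), is.numeric(threshold),
            length(threshold) == 1L)
  if (is.na(threshold) || threshold < 0 || threshold > 255 ||
      threshold != as.integer(threshold))
    stop("'threshold' must be an integer in [0, 255]")
  structure(list(include = projection_8bit > threshold,
                 threshold = as.integer(threshold)),
            class = "gp_mask")
}

is_gp_mask <- function(x) inherits(x, "gp_mask")

#' @export
print.gp_mask <- function(x, ...) {
  cat(sprintf("<gp_mask> %d / %d pixels included (threshold %d on 0-255)\n",
              sum(x$include), length(x$include), x$threshold))
  invisible(x)
}

#' Per-channel background estimate from the dark area
#'
#' The background of each channel plane is the mean (or median) intensity
#' over the pixels *excluded* by the mask — the dark area of that slice.
#' Estimating per channel corrects minor variations in background level
#' across the spectrum.
#'
#' @param stack A [spectral_stack()].
#' @param mask A [compute_mask()] result; must exclude at least one pixel.
#' @param statistic `"mean"` (default) or `"median"` (for heavy-tailed
#'   backgrounds).
#' @return Numeric vector of per-channel background levels, one per channel.
#' @export
estimate_background <- function(stack, mask, statistic = c("mean", "median")) {
  stopifnot(is_spectral_stack(stack), is_gp_mask(mask))
  statistic <- match.arg(statistic)
  if (!identical(dim(mask$include), dim(stack$data)[1:2]))
    stop("mask and stack have different spatial dimensions")
  dark <- !mask$include
  if (!any(dark))
    stop("no dark area available; disable background subtraction or lower the mask threshold")
  fun <- if (statistic == "mean") mean else stats::median
  vapply(seq_len(stack$axis$n_channels),
         function(k) fun(stack$data[, , k][dark]), numeric(1))
}

#' Subtract the per-channel background inside the mask
#'
#' For masked-in pixels, each channel value becomes
#' `max(value - background[k], 0)`; clipping at zero keeps the stack in the
#' nonnegative model space. Masked-out pixels are left bitwise unchanged.
#'
#' @param stack A [spectral_stack()].
#' @param background Per-channel background vector (finite, nonnegative),
#'   e.g. from [estimate_background()].
#' @param mask A [compute_mask()] result.
#' @return A new background-subtracted [spectral_stack()].
#' @export
subtract_background <- function(stack, background, mask) {
  stopifnot(is_spectral_stack(stack), is.numeric(background), is_gp_mask(mask))
  n <- stack$axis$n_channels
  if (length(background) != n)
    stop(sprintf("background has %d values but the stack has %d channels",
                 length(background), n))
  if (anyNA(background) || any(!is.finite(background) | background < 0))
    stop("background levels must be finite and nonnegative")
  if (!identical(dim(mask$include), dim(stack$data)[1:2]))
    stop("mask and stack have different spatial dimensions")
  d <- stack$data
  inc <- mask$include
  for (k in seq_len(n)) {
    plane <- d[, , k]
    plane[inc] <- pmax(plane[inc] - background[k], 0)
    d[, , k] <- plane
  }
  spectral_stack(d, stack$axis, stack$source)
}
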