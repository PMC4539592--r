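# Generalized polarization (GP).
#
# GP = (I_B - I_R) / (I_B + I_R), where I_B and I_R are the emission
# intensities at a blue-shifted reference wavelength lambda_Lo (emission
# maximum of the probe in a liquid-ordered membrane) and a red-shifted
# reference lambda_Ld (liquid-disordered). GP is a relative lipid-packing
# index in [-1, 1]: ordered, tightly packed membranes blue-shift the probe
# emission and push GP up; disordered membranes red-shift it and push GP
# down. For plug-in parity both intensities are divided by 255 before the
# ratio; the normalization cancels and is value-neutral.

#' Probe wavelength preset
#'
#' The pair of reference wavelengths a probe is read out at. Built-in
#' presets: `"c-laurdan"` (lambda_Lo = 440 nm, lambda_Ld = 490 nm) and
#' `"di-4-aneppdhq"` (lambda_Lo = 565 nm, lambda_Ld = 605 nm). Any other
#' name defines a custom preset and requires both wavelengths. GP values
#' are relative: they depend on this choice, and only results obtained with
#' the same preset are comparable.
#'
#' @param name Preset name.
#' @param lambda_lo Blue-shifted reference wavelength (nm); the intensity
#'   read here is I_B.
#' @param lambda_ld Red-shifted reference wavelength (nm); the intensity
#'   read here is I_R.
#' @return An object of class `probe_preset`.
#' @examples
#' probe_preset("c-laurdan")
#' probe_preset("custom", lambda_lo = 450, lambda_ld = 500)
#' @export
probe_preset <- function(name = "c-laurdan", lambda_lo = NULL, lambda_ld = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  known <- list("c-laurdan" = c(lo = 440, ld = 490),
                "di-4-aneppdhq" = c(lo = 565, ld = 605))
  if (name %in% names(known)) {
    if (is.null(lambda_lo)) lambda_lo <- known[[name]][["lo"]]
    if (is.null(lambda_ld)) lambda_ld <- known[[name]][["ld"]]
  }
  if (is.null(lambda_lo) || is.null(lambda_ld))
    stop(sprintf("preset '%s' is not built in; supply lambda_lo and lambda_ld",
                 name))
  stopifnot(is.numeric(lambda_lo), is.numeric(lambda_ld),
            is.finite(lambda_lo), is.finite(lambda_ld))
  if (lambda_lo == lambda_ld)
    stop("lambda_lo and lambda_ld must differ")
  structure(list(name = name, lambda_lo = as.numeric(lambda_lo),
                 lambda_ld = as.numeric(lambda_ld)),
            class = "probe_preset")
}

is_probe_preset <- function(x) inherits(x, "probe_preset")

#' @export
print.probe_preset <- function(x, ...) {
  cat(sprintf("<probe_preset> %s: lambda_Lo = %g nm (I_B), lambda_Ld = %g nm (I_R)\n",
              x$name, x$lambda_lo, x$lambda_ld))
  invisible(x)
}

#' Generalized polarization of an intensity pair
#'
#' `GP = (I_B/255 - I_R/255) / (I_B/255 + I_R/255)`; the division by 255 is
#' kept for parity with the original 8-bit plug-in convention and cancels
#' exactly. Vectorized. A pixel with no signal at either wavelength
#' (`I_B + I_R = 0`) has undefined GP and yields `NaN` — never 0, which is a
#' legal GP value.
#'
#' @param i_b Blue-shifted intensity (at lambda_Lo), nonnegative.
#' @param i_r Red-shifted intensity (at lambda_Ld), nonnegative.
#' @return GP value(s) in `[-1, 1]`, or `NaN` where undefined.
#' @export
gp_value <- function(i_b, i_r) {
  stopifnot(is.numeric(i_b), is.numeric(i_r), length(i_b) == length(i_r))
  if (any(i_b < 0, na.rm = TRUE) || any(i_r < 0, na.rm = TRUE))
    stop("intensities must be nonnegative (preprocessing clips at zero)")
  b <- i_b / 255
  r <- i_r / 255
  s <- b + r
  gp <- ifelse(s > 0, (b - r) / s, NaN)
  gp[is.na(i_b) | is.na(i_r)] <- NaN
  gp
}

#' Direct sampling of the GP readout intensities
#'
#' The non-fitting readout: I_B is the recorded intensity of the channel
#' whose center wavelength is nearest lambda_Lo, I_R likewise for
#' lambda_Ld (ties resolve to the lower-wavelength channel, see
#' [nearest_channel()]).
#'
#' @param spectrum Intensities, one per channel.
#' @param axis The [wavelength_axis()] of the spectrum.
#' @param preset A [probe_preset()]; both wavelengths must lie within the
#'   axis range.
#' @return Named vector `c(I_B=, I_R=)`.
#' @export
direct_sample_intensities <- function(spectrum, axis, preset) {
  stopifnot(is.numeric(spectrum), is_wavelength_axis(axis), is_probe_preset(preset))
  if (length(spectrum) != axis$n_channels)
    stop(sprintf("spectrum has %d values but the axis declares %d channels",
                 length(spectrum), axis$n_channels))
  c(I_B = spectrum[nearest_channel(axis, preset$lambda_lo)],
    I_R = spectrum[nearest_channel(axis, preset$lambda_ld)])
}

#' Analysis configuration
#'
#' Bundles every tunable of the GP pipeline. Validated on construction and
#' serialized into each output directory for provenance.
#'
#' @param axis A [wavelength_axis()].
#' @param preset A [probe_preset()] (default C-Laurdan, 440/490 nm).
#' @param method `"direct"` (channel sampling), `"gaussian"` or
#'   `"gamma_variate"` (whole-spectrum fitting).
#' @param mask_threshold Mask threshold on the 8-bit Z-projection scale
#'   (0--255, default 15).
#' @param background_subtraction Subtract the per-channel dark-area
#'   background before the readout (default `TRUE`).
#' @param background_statistic `"mean"` (default) or `"median"`.
#' @param r2_tolerance Minimum R-squared for a fitted pixel to enter the GP
#'   map (0--1, default 0.8); pixels with `r_squared >= r2_tolerance` are
#'   included. Ignored for the direct method.
#' @param bin_width GP histogram bin width (default 0.02, resolving phase
#'   separations of 0.3 GP units with >= 15 bins between modes).
#' @param sensitivity_correction Optional per-channel multiplier vector
#'   (default `NULL`, i.e. identity: factory-normalized channels).
#' @param max_iterations Optimizer iteration cap per pixel fit.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(axis,
                            preset = probe_preset("c-laurdan"),
                            method = c("direct", "gaussian", "gamma_variate"),
                            mask_threshold = 15L,
                            background_subtraction = TRUE,
                            background_statistic = c("mean", "median"),
                            r2_tolerance = 0.8,
                            bin_width = 0.02,
                            sensitivity_correction = NULL,
                            max_iterations = 200L) {
  method <- match.arg(method)
  background_statistic <- match.arg(background_statistic)
  stopifnot(is_wavelength_axis(axis), is_probe_preset(preset),
            is.logical(background_subtraction), length(background_subtraction) == 1L,
            is.numeric(r2_tolerance), length(r2_tolerance) == 1L,
            is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0)
  if (is.na(mask_threshold) || mask_threshold < 0 || mask_threshold > 255)
    stop("'mask_threshold' must be in [0, 255]")
  if (is.na(r2_tolerance) || r2_tolerance < 0 || r2_tolerance > 1)
    stop("'r2_tolerance' must be in [0, 1]")
  # both readout wavelengths must be reachable on this axis
  nearest_channel(axis, preset$lambda_lo)
  nearest_channel(axis, preset$lambda_ld)
  if (!is.null(sensitivity_correction)) {
    if (length(sensitivity_correction) != axis$n_channels ||
        any(!is.finite(sensitivity_correction) | sensitivity_correction <= 0))
      stop("'sensitivity_correction' must be one positive factor per channel")
  }
  structure(list(axis = axis, preset = preset, method = method,
                 mask_threshold = as.integer(mask_threshold),
                 background_subtraction = background_subtraction,
                 background_statistic = background_statistic,
                 r2_tolerance = r2_tolerance, bin_width = bin_width,
                 sensitivity_correction = sensitivity_correction,
                 max_iterations = as.integer(max_iterations)),
            class = "analysis_config")
}

is_analysis_config <- function(x) inherits(x, "analysis_config")

#' Compute a GP map from a spectral stack
#'
#' The full per-image pipeline:
#' optional sensitivity correction, Z-projection, 8-bit rescale,
#' threshold mask, optional per-channel background subtraction inside the
#' mask, then a per-pixel readout of I_B and I_R — either by direct channel
#' sampling or by fitting the chosen line shape to the whole spectrum and
#' evaluating the curve at the preset wavelengths — followed by the
#' R-squared inclusion filter (fitting methods only) and the GP ratio.
#' Deterministic given the stack and configuration.
#'
#' @param stack A [spectral_stack()].
#' @param config An [analysis_config()].
#' @return An object of class `gp_map`: matrix `gp` (`NaN` outside the mask,
#'   where a fit failed, or below the R-squared tolerance), matrix `r2`
#'   (fitting methods; `NaN` where not fitted), the `mask`, `method`,
#'   `preset`, `axis`, per-channel `background` (or `NULL`), and the
#'   counts `n_fit_failures` and `n_below_tolerance`.
#' @export
compute_gp_map <- function(stack, config) {
  stopifnot(is_spectral_stack(stack), is_analysis_config(config))
  if (stack$axis$n_channels != config$axis$n_channels)
    stop("stack and configuration disagree on the number of channels")
  if (!is.null(config$sensitivity_correction))
    stack <- apply_sensitivity_correction(stack, config$sensitivity_correction)
  proj <- z_project(stack)
  mask <- compute_mask(to_8bit_scale(proj), config$mask_threshold)
  background <- NULL
  if (config$background_subtraction) {
    background <- estimate_background(stack, mask, config$background_statistic)
    stack <- subtract_background(stack, background, mask)
  }
  d <- dim(stack$data)
  gp <- array(NaN, d[1:2])
  r2 <- if (config$method != "direct") array(NaN, d[1:2]) else NULL
  n_fail <- 0L
  n_below <- 0L
  idx <- which(mask$include, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    warning("mask is empty: no pixel exceeds the threshold; GP map is all NaN")
  for (i in seq_len(nrow(idx))) {
    spec <- stack$data[idx[i, 1L], idx[i, 2L], ]
    if (config$method == "direct") {
      ii <- direct_sample_intensities(spec, stack$axis, config$preset)
      gp[idx[i, 1L], idx[i, 2L]] <- gp_value(ii[["I_B"]], ii[["I_R"]])
    } else {
      fit <- fit_spectrum(spec, stack$axis, config$method,
                          config$max_iterations)
      if (!fit$converged) { n_fail <- n_fail + 1L; next }
      r2[idx[i, 1L], idx[i, 2L]] <- fit$r_squared
      if (fit$r_squared < config$r2_tolerance) { n_below <- n_below + 1L; next }
      gp[idx[i, 1L], idx[i, 2L]] <-
        gp_value(evaluate_fit(fit, config$preset$lambda_lo),
                 evaluate_fit(fit, config$preset$lambda_ld))
    }
  }
  structure(list(gp = gp, r2 = r2, mask = mask, method = config$method,
                 preset = config$preset, axis = stack$axis,
                 background = background,
                 n_fit_failures = n_fail, n_below_tolerance = n_below),
            class = "gp_map")
}

is_gp_map <- function(x) inherits(x, "gp_map")

#' @export
print.gp_map <- function(x, ...) {
  v <- x$gp[is.finite(x$gp)]
  cat(sprintf("<gp_map> %d x %d, method %s, preset %s (%g/%g nm)\n",
              nrow(x$gp), ncol(x$gp), x$method, x$preset$name,
              x$preset$lambda_lo, x$preset$lambda_ld))
  if (length(v))
    cat(sprintf("  %d finite pixels: mean %.4f, sd %.4f, range [%.4f, %.4f]\n",
                length(v), mean(v), stats::sd(v), min(v), max(v)))
  else cat("  no finite GP values\n")
  if (x$method != "direct")
    cat(sprintf("  fit failures: %d, below R^2 tolerance: %d\n",
                x$n_fit_failures, x$n_below_tolerance))
  invisible(x)
}

#' GP histogram and summary statistics
#'
#' Uniform-bin histogram of the finite GP values over `[-1, 1]` (bins are
#' left-closed, right-open except the last, which is closed) plus the
#' summary statistics reported with a GP map: mean, SD, median, and the
#' medians of the positive-GP and negative-GP subpopulations — the
#' ordered and disordered "phases" of a bimodal GP distribution
#' (`NaN` when a subset is empty).
#'
#' @param x A [compute_gp_map()] result or a numeric vector of GP values.
#' @param bin_width Bin width in GP units (default 0.02).
#' @return An object of class `gp_histogram`: `bin_edges`, `counts`,
#'   `mean`, `sd`, `median`, `median_positive`, `median_negative`,
#'   `n_pixels`.
#' @export
gp_histogram <- function(x, bin_width = 0.02) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0)
  gp <- if (is_gp_map(x)) x$gp else x
  stopifnot(is.numeric(gp))
  v <- gp[is.finite(gp)]
  n_bins <- max(1L, as.integer(ceiling(2 / bin_width - 1e-9)))
  edges <- -1 + bin_width * (0:n_bins)
  edges[n_bins + 1L] <- max(edges[n_bins + 1L], 1)
  if (length(v)) {
    bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
    counts <- tabulate(bin, nbins = n_bins)
  } else counts <- integer(n_bins)
  med <- function(z) if (length(z)) stats::median(z) else NaN
  structure(list(bin_edges = edges, counts = counts,
                 mean = if (length(v)) mean(v) else NaN,
                 sd = if (length(v) > 1L) stats::sd(v) else NaN,
                 median = med(v),
                 median_positive = med(v[v > 0]),
                 median_negative = med(v[v < 0]),
                 n_pixels = length(v)),
            class = "gp_histogram")
}

is_gp_histogram <- function(x) inherits(x, "gp_histogram")

#' @export
print.gp_histogram <- function(x, ...) {
  cat(sprintf(paste0("<gp_histogram> %d pixels in %d bins: mean %.4f, sd %.4f, ",
                     "median %.4f (+phase %.4f / -phase %.4f)\n"),
              x$n_pixels, length(x$counts), x$mean, x$sd, x$median,
              x$median_positive, x$median_negative))
  invisible(x)
}

#' @export
as.data.frame.gp_histogram <- function(x, ...) {
  n <- length(x$counts)
  data.frame(bin_left = x$bin_edges[seq_len(n)],
             bin_right = x$bin_edges[seq_len(n) + 1L],
             count = x$counts)
}

#' Compare the readout methods on one stack
#'
#' Runs [compute_gp_map()] with identical preprocessing settings for each
#' requested method and tabulates per-method GP statistics, mean R-squared
#' and fit-failure counts — and per-phase statistics when a ground-truth
#' phase labeling is available (synthetic scenes).
#'
#' @param stack A [spectral_stack()].
#' @param config An [analysis_config()]; its `method` field is overridden.
#' @param methods Character vector of methods to run.
#' @param phase_label Optional integer matrix of ground-truth phase ids
#'   (0 = no phase), as produced by [render_stack()].
#' @return List with `maps` (named list of `gp_map`), `summary` (one row per
#'   method) and `per_phase` (one row per method x phase, or `NULL`).
#' @export
compare_methods <- function(stack, config,
                            methods = c("direct", "gaussian", "gamma_variate"),
                            phase_label = NULL) {
  stopifnot(is_spectral_stack(stack), is_analysis_config(config))
  methods <- match.arg(methods, several.ok = TRUE)
  maps <- lapply(methods, function(m) {
    cfg <- config
    cfg$method <- m
    compute_gp_map(stack, cfg)
  })
  names(maps) <- methods
  summary <- do.call(rbind, lapply(methods, function(m) {
    g <- maps[[m]]$gp[is.finite(maps[[m]]$gp)]
    r2 <- maps[[m]]$r2
    data.frame(method = m,
               n_pixels = length(g),
               mean_gp = if (length(g)) mean(g) else NaN,
               sd_gp = if (length(g) > 1L) stats::sd(g) else NaN,
               mean_r2 = if (is.null(r2)) NA_real_ else mean(r2[is.finite(r2)]),
               n_fit_failures = maps[[m]]$n_fit_failures,
               n_below_tolerance = maps[[m]]$n_below_tolerance)
  }))
  per_phase <- NULL
  if (!is.null(phase_label)) {
    stopifnot(is.matrix(phase_label),
              identical(dim(phase_label), dim(maps[[1L]]$gp)))
    ids <- sort(unique(phase_label[phase_label > 0]))
    per_phase <- do.call(rbind, lapply(methods, function(m) {
      do.call(rbind, lapply(ids, function(ph) {
        g <- maps[[m]]$gp[phase_label == ph]
        g <- g[is.finite(g)]
        data.frame(method = m, phase = ph, n_pixels = length(g),
                   mean_gp = if (length(g)) mean(g) else NaN,
                   sd_gp = if (length(g) > 1L) stats::sd(g) else NaN)
      }))
    }))
  }
  list(maps = maps, summary = summary, per_phase = per_phase)
}
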