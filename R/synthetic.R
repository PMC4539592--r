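# Synthetic vesicle scenes with analytic ground truth.
#
# Emulates the equatorial-plane image of a giant vesicle: a bright ring
# (the membrane cross-section) on a dark background, the ring divided into
# angular sectors that model coexisting membrane phases. Every ring pixel
# of a sector carries the same smooth single-peak emission spectrum
# (Gaussian or gamma variate, peak blue-shifted for ordered and red-shifted
# for disordered phases); a flat or per-channel background and shot-type
# noise complete the scene. Because the generating spectra are closed-form,
# the GP of every pixel is known analytically and the whole pipeline can be
# validated against it.

#' Synthetic vesicle scene
#'
#' Builds the parametric description of a ring ("equatorial-plane vesicle")
#' scene whose angular sectors carry distinct spectral phases. The defaults
#' are the package's reference conditions: a 128 x 128 image, two equal
#' sectors with Gaussian emission peaked at 440 nm (ordered, Lo) and 490 nm
#' (disordered, Ld), sigma = 25 nm, peak amplitude 400 counts over a flat
#' background of 5 counts per channel, on the 32-channel 8.9 nm axis
#' starting at 415 nm.
#'
#' @param image_size Image side length in pixels (square image).
#' @param ring_radius Ring radius in pixels (default 30% of the side).
#' @param ring_thickness Radial thickness of the ring in pixels.
#' @param n_phases Number of equal angular sectors. With the default
#'   Gaussian models, sector peaks are spaced evenly from 440 to 490 nm
#'   (a single sector peaks at 440 nm: a uniform ordered vesicle).
#' @param peak_amplitude Peak expected signal per phase, in counts. Under
#'   Poisson noise the peak SNR is `sqrt(peak_amplitude)`.
#' @param background_level Background per channel: a scalar (flat) or a
#'   vector of length `n_channels`. Must stay below `peak_amplitude`.
#' @param sigma_nm Spectral width of the default Gaussian phase models.
#' @param axis A [wavelength_axis()].
#' @param phase_models Optional list overriding the default models: one
#'   element per phase, each `list(model_kind =, params =)` with params as
#'   in [gaussian_model()] / [gamma_variate_model()] (the `A` field sets
#'   that phase's peak amplitude).
#' @return An object of class `synthetic_scene`.
#' @export
make_two_phase_vesicle <- function(image_size = 128L,
                                   ring_radius = NULL,
                                   ring_thickness = 6L,
                                   n_phases = 2L,
                                   peak_amplitude = 400,
                                   background_level = 5,
                                   sigma_nm = 25,
                                   axis = wavelength_axis(415, 8.9, 32),
                                   phase_models = NULL) {
  stopifnot(is.numeric(image_size), image_size >= 8,
            is.numeric(n_phases), n_phases >= 1,
            is.numeric(peak_amplitude), peak_amplitude > 0,
            is.numeric(background_level),
            is_wavelength_axis(axis))
  image_size <- as.integer(image_size)
  n_phases <- as.integer(n_phases)
  if (is.null(ring_radius)) ring_radius <- 0.3 * image_size
  center <- (image_size + 1) / 2
  if (center + ring_radius + ring_thickness / 2 > image_size ||
      ring_radius - ring_thickness / 2 <= 0)
    stop("ring does not fit inside the image")
  if (!length(background_level) %in% c(1L, axis$n_channels))
    stop("'background_level' must be a scalar or one value per channel")
  if (any(background_level < 0) || any(!is.finite(background_level)))
    stop("'background_level' must be finite and nonnegative")

  if (is.null(phase_models)) {
    peaks <- if (n_phases == 1L) 440 else seq(440, 490, length.out = n_phases)
    phase_models <- lapply(peaks, function(mu)
      list(model_kind = "gaussian",
           params = c(A = peak_amplitude, mu = mu, sigma = sigma_nm)))
  }
  if (length(phase_models) != n_phases)
    stop("'phase_models' must have one entry per phase")
  bounds <- 2 * pi * (0:n_phases) / n_phases     # sectors partition [0, 2*pi)
  phases <- lapply(seq_len(n_phases), function(i) {
    m <- phase_models[[i]]
    stopifnot(m$model_kind %in% c("gaussian", "gamma_variate"))
    if (m$params[["A"]] <= max(background_level))
      stop("phase amplitudes must exceed the background level")
    list(name = paste0("phase", i), model_kind = m$model_kind,
         params = m$params,
         theta_start = bounds[i], theta_end = bounds[i + 1L])
  })
  structure(list(image_size = c(image_size, image_size),
                 ring_center = c(center, center),
                 ring_radius = ring_radius,
                 ring_thickness = ring_thickness,
                 phases = phases,
                 background_level = background_level,
                 axis = axis),
            class = "synthetic_scene")
}

is_synthetic_scene <- function(x) inherits(x, "synthetic_scene")

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d, ring r = %.1f (t = %g), %d phase(s)\n",
              x$image_size[1L], x$image_size[2L], x$ring_radius,
              x$ring_thickness, length(x$phases)))
  invisible(x)
}

#' Analytic GP of a spectral model
#'
#' The ground-truth GP of a closed-form emission spectrum under a given
#' probe preset: `gp_value(I(lambda_Lo), I(lambda_Ld))` with the model
#' evaluated continuously. With `axis` supplied the model is instead
#' evaluated at the centers of the channels nearest the preset wavelengths
#' — the exact quantity the direct-sampling readout estimates, which
#' differs from the continuous GP by the channel-discretization offset.
#'
#' @param model_kind `"gaussian"` or `"gamma_variate"`.
#' @param params Model parameters (see [gaussian_model()],
#'   [gamma_variate_model()]).
#' @param preset A [probe_preset()].
#' @param axis Optional [wavelength_axis()] for the channel-sampled variant.
#' @return The GP value (`NaN` if the model vanishes at both wavelengths).
#' @export
analytic_gp <- function(model_kind, params, preset, axis = NULL) {
  stopifnot(model_kind %in% c("gaussian", "gamma_variate"), is_probe_preset(preset))
  model <- switch(model_kind, gaussian = gaussian_model,
                  gamma_variate = gamma_variate_model)
  lo <- preset$lambda_lo
  ld <- preset$lambda_ld
  if (!is.null(axis)) {
    lo <- axis$centers_nm[nearest_channel(axis, lo)]
    ld <- axis$centers_nm[nearest_channel(axis, ld)]
  }
  gp_value(model(lo, params), model(ld, params))
}

#' Render a synthetic scene into a spectral stack
#'
#' Every ring pixel receives its sector's model spectrum sampled at the
#' channel centers; all pixels receive the background; noise is applied
#' channel-wise. Rendering is deterministic given `(scene, noise, seed)`;
#' the caller's RNG state is left untouched.
#'
#' @param scene A [make_two_phase_vesicle()] scene.
#' @param noise `"none"`, `"poisson"` (shot noise: each recorded value is a
#'   Poisson draw with the noiseless value as its expectation, so the peak
#'   SNR is `sqrt(peak_amplitude)`), or `"gaussian"` (additive,
#'   sd `gaussian_sd`, clipped at zero).
#' @param seed Integer RNG seed; required for noisy rendering.
#' @param gaussian_sd Standard deviation for `noise = "gaussian"`.
#' @param preset The [probe_preset()] used for the analytic per-pixel
#'   ground-truth GP.
#' @return List with `stack` (a [spectral_stack()]) and `truth`: matrix
#'   `phase_label` (0 = off-ring, else the 1-based sector id), matrix
#'   `gp_true` (analytic continuous GP, `NaN` off the ring), and
#'   `spectra_params` (per-sector model description).
#' @export
render_stack <- function(scene, noise = c("none", "poisson", "gaussian"),
                         seed = NULL, gaussian_sd = 1,
                         preset = probe_preset("c-laurdan")) {
  stopifnot(is_synthetic_scene(scene))
  noise <- match.arg(noise)
  if (noise != "none") {
    if (is.null(seed)) stop("noisy rendering requires a seed")
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  nr <- scene$image_size[1L]; nc <- scene$image_size[2L]
  n_ch <- scene$axis$n_channels
  ctr <- scene$axis$centers_nm
  bg <- rep_len(scene$background_level, n_ch)

  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dy <- row - scene$ring_center[1L]
  dx <- col - scene$ring_center[2L]
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) + 2 * pi) %% (2 * pi)
  on_ring <- abs(r - scene$ring_radius) <= scene$ring_thickness / 2

  phase_label <- array(0L, c(nr, nc))
  gp_true <- array(NaN, c(nr, nc))
  sector_spectrum <- matrix(NA_real_, length(scene$phases), n_ch)
  for (i in seq_along(scene$phases)) {
    ph <- scene$phases[[i]]
    model <- switch(ph$model_kind, gaussian = gaussian_model,
                    gamma_variate = gamma_variate_model)
    sector_spectrum[i, ] <- model(ctr, ph$params)
    inside <- on_ring & theta >= ph$theta_start & theta < ph$theta_end
    phase_label[inside] <- i
    gp_true[inside] <- analytic_gp(ph$model_kind, ph$params, preset)
  }

  data <- array(rep(bg, each = nr * nc), c(nr, nc, n_ch))
  for (i in seq_along(scene$phases)) {
    sel <- phase_label == i
    for (k in seq_len(n_ch))
      data[, , k][sel] <- data[, , k][sel] + sector_spectrum[i, k]
  }
  if (noise == "poisson") {
    data[] <- stats::rpois(length(data), data)
  } else if (noise == "gaussian") {
    data[] <- pmax(data + stats::rnorm(length(data), sd = gaussian_sd), 0)
  }
  list(stack = spectral_stack(data, scene$axis, source = "synthetic"),
       truth = list(phase_label = phase_label, gp_true = gp_true,
                    spectra_params = scene$phases))
}
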