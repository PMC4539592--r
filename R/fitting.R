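# Per-pixel spectral line-shape models and fitting.
#
# Two single-peak models reduce a pixel's sampled emission spectrum to a
# continuous curve that can be read out at arbitrary wavelengths:
#
#   gaussian       I(l) = A * exp(-(l - mu)^2 / (2 sigma^2))        (no offset)
#   gamma_variate  I(l) = A * ((l-l0)/(a*b))^a * exp(a - (l-l0)/b)  for l > l0
#                        = 0                                        for l <= l0
#
# The gamma variate is peak-normalized: its maximum is A, attained at
# l0 + a*b. For small shape a it is right-skewed — the asymmetry typical of
# ordered-phase probe spectra — and for large a it approaches a Gaussian
# with sd sqrt(a)*b, so the family contains symmetric spectra as a limit.

#' Gaussian (no-offset) spectral model
#'
#' @param lambda_nm Wavelength(s) in nm.
#' @param params Named numeric vector `c(A=, mu=, sigma=)`: peak amplitude
#'   (intensity units, > 0), peak wavelength (nm), and standard-deviation
#'   width (nm, > 0). There is no additive offset term; the background is
#'   removed in preprocessing, not modeled here.
#' @return Model intensity at each `lambda_nm`.
#' @export
gaussian_model <- function(lambda_nm, params) {
  p <- check_params(params, c("A", "mu", "sigma"))
  if (p[["A"]] <= 0 || p[["sigma"]] <= 0)
    stop("gaussian parameters require A > 0 and sigma > 0")
  p[["A"]] * exp(-(lambda_nm - p[["mu"]])^2 / (2 * p[["sigma"]]^2))
}

#' Gamma Variate spectral model
#'
#' Peak-normalized gamma-variate line shape: zero at and below the onset
#' `lambda0`, rising to its maximum `A` at `lambda0 + alpha*beta`, with a
#' heavier red tail than blue tail for small `alpha` (right skew). The
#' implementation evaluates the exponent as
#' `alpha * (log1p(d) - d)` with `d = (lambda - peak)/peak_offset`, which is
#' numerically stable up to the near-Gaussian regime of very large `alpha`.
#'
#' @param lambda_nm Wavelength(s) in nm.
#' @param params Named numeric vector `c(A=, lambda0=, alpha=, beta=)`:
#'   peak amplitude (> 0), onset wavelength (nm), dimensionless shape (> 0),
#'   and scale in nm (> 0).
#' @return Model intensity at each `lambda_nm`.
#' @export
gamma_variate_model <- function(lambda_nm, params) {
  p <- check_params(params, c("A", "lambda0", "alpha", "beta"))
  if (p[["A"]] <= 0 || p[["alpha"]] <= 0 || p[["beta"]] <= 0)
    stop("gamma variate parameters require A > 0, alpha > 0 and beta > 0")
  x <- lambda_nm - p[["lambda0"]]
  out <- numeric(length(lambda_nm))
  pos <- x > 0
  if (any(pos)) {
    m <- p[["alpha"]] * p[["beta"]]          # peak offset from onset
    d <- (x[pos] - m) / m
    out[pos] <- p[["A"]] * exp(p[["alpha"]] * (log1p(d) - d))
  }
  out
}

check_params <- function(params, wanted) {
  if (!is.numeric(params) || is.null(names(params)) ||
      !all(wanted %in% names(params)))
    stop(sprintf("params must be a named numeric vector with fields %s",
                 paste(wanted, collapse = ", ")))
  if (any(!is.finite(params[wanted])))
    stop("model parameters must be finite")
  params[wanted]
}

#' Coefficient of determination of a fit
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares about the observed
#' mean: 1 for a perfect fit, 0 for a fit no better than the mean, negative
#' for worse. For a constant observed vector the statistic is undefined and
#' `NaN` is returned (the fitter then marks the pixel as not converged).
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return Scalar in `(-Inf, 1]`, or `NaN` when undefined.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted), length(observed) >= 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NaN)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Initial parameter guess for a spectral fit
#'
#' Moment-based starting values. For the Gaussian: amplitude is the maximum
#' intensity, peak the intensity-weighted mean wavelength, and width the
#' intensity-weighted standard deviation, floored at half a channel width so
#' a single bright channel still yields a usable (if degenerate) guess. For
#' the gamma variate: the onset starts one channel width blue of the
#' detection window, and shape/scale come from matching the weighted mean
#' and variance of the spectrum to those of a gamma density with shape
#' `alpha + 1` and scale `beta` (mean `lambda0 + (alpha+1) beta`, variance
#' `(alpha+1) beta^2`).
#'
#' @param spectrum Nonnegative intensities, one per channel; at least one
#'   strictly positive.
#' @param axis The [wavelength_axis()] of the spectrum.
#' @param model_kind `"gaussian"` or `"gamma_variate"`.
#' @return Named parameter vector for the requested model.
#' @export
initial_guess <- function(spectrum, axis,
                          model_kind = c("gaussian", "gamma_variate")) {
  model_kind <- match.arg(model_kind)
  stopifnot(is.numeric(spectrum), is_wavelength_axis(axis),
            length(spectrum) == axis$n_channels)
  if (anyNA(spectrum) || any(spectrum < 0))
    stop("spectrum must be nonnegative")
  if (all(spectrum == 0)) stop("empty spectrum")
  ctr <- axis$centers_nm
  w <- spectrum / sum(spectrum)
  mu <- sum(w * ctr)
  sdev <- sqrt(sum(w * (ctr - mu)^2))
  sdev <- max(sdev, axis$width_nm / 2)
  if (model_kind == "gaussian")
    return(c(A = max(spectrum), mu = mu, sigma = sdev))
  lambda0 <- axis$start_nm - axis$width_nm
  mx <- mu - lambda0
  alpha <- max(mx^2 / sdev^2 - 1, 0.25)
  beta <- sdev^2 / mx
  c(A = max(spectrum), lambda0 = lambda0, alpha = alpha, beta = beta)
}

# Internal fitting coordinates for the gamma variate: (A, m, s, q) with
# m = peak wavelength (l0 + a b), s = sd-like width (sqrt(a) b) and
# q = 1/sqrt(a) (skew; q -> 0 is the Gaussian limit). In the raw
# (l0, a, b) coordinates near-symmetric spectra sit on a long curved
# ridge (l0 -> -Inf, a -> Inf) on which Levenberg-Marquardt stalls; in
# (m, s, q) the same limit is a smooth interior path and the fit
# converges in a handful of iterations.
gv_msq_eval <- function(lambda_nm, p) {
  z <- (lambda_nm - p[2L]) / p[3L]
  qz <- p[4L] * z
  out <- numeric(length(lambda_nm))
  pos <- qz > -1
  out[pos] <- p[1L] * exp((log1p(qz[pos]) - qz[pos]) / p[4L]^2)
  out
}

gv_raw_from_msq <- function(p) {
  c(A = p[[1L]], lambda0 = p[[2L]] - p[[3L]] / p[[4L]],
    alpha = 1 / p[[4L]]^2, beta = p[[3L]] * p[[4L]])
}

gv_msq_from_raw <- function(p) {
  q <- 1 / sqrt(p[["alpha"]])
  c(A = p[["A"]], m = p[["lambda0"]] + p[["alpha"]] * p[["beta"]],
    s = sqrt(p[["alpha"]]) * p[["beta"]], q = q)
}

#' Fit a single-pixel emission spectrum
#'
#' Bounded Levenberg-Marquardt least squares of the chosen line shape to the
#' spectrum sampled at the channel centers, started from [initial_guess()].
#' Uniform weights are used (no per-channel variance model). Optimizer
#' failures and degenerate spectra are reported through `converged = FALSE`
#' rather than as errors, since a map involves thousands of independent
#' pixel fits. If the first attempt fails or fits poorly, a small fixed set
#' of deterministic restarts (width halved/doubled, peak shifted by one
#' channel) is tried and the best result kept, so fitting is fully
#' deterministic.
#'
#' For the gamma variate the optimizer works internally in
#' (amplitude, peak, width, skew) coordinates in which the symmetric-
#' spectrum limit is well conditioned; results are reported as
#' `c(A, lambda0, alpha, beta)`. The onset is constrained blue of the
#' detection window (`lambda0 <= first center - 1 nm`): emission onsets sit
#' below the recorded range, whose blue tail the detector cuts off.
#'
#' @param spectrum Nonnegative intensities, one per channel (background
#'   already subtracted).
#' @param axis The [wavelength_axis()] of the spectrum.
#' @param model_kind `"gaussian"` or `"gamma_variate"`.
#' @param max_iterations Maximum optimizer iterations (default 200).
#' @return An object of class `fit_result`: `model_kind`, `params` (named
#'   vector), `r_squared`, `converged`, `n_points`.
#' @export
fit_spectrum <- function(spectrum, axis,
                         model_kind = c("gaussian", "gamma_variate"),
                         max_iterations = 200L) {
  model_kind <- match.arg(model_kind)
  stopifnot(is.numeric(spectrum), is_wavelength_axis(axis))
  if (length(spectrum) != axis$n_channels)
    stop(sprintf("spectrum has %d values but the axis declares %d channels",
                 length(spectrum), axis$n_channels))
  failed <- structure(list(model_kind = model_kind, params = NULL,
                           r_squared = NaN, converged = FALSE,
                           n_points = length(spectrum)),
                      class = "fit_result")
  if (anyNA(spectrum) || any(spectrum < 0) || all(spectrum == 0) ||
      stats::var(spectrum) == 0)
    return(failed)

  guess <- initial_guess(spectrum, axis, model_kind)
  ctr <- axis$centers_nm
  span <- ctr[axis$n_channels] - ctr[1L]
  starts <- fit_starts(guess, model_kind, axis)
  best <- failed
  for (p0 in starts) {
    res <- fit_once(spectrum, ctr, span, axis, p0, model_kind, max_iterations)
    if (res$converged &&
        (!best$converged || res$r_squared > best$r_squared)) best <- res
    # restarts are a fallback: stop as soon as an attempt converges to
    # anything better than a grossly wrong local optimum
    if (best$converged && best$r_squared > 0.2) break
  }
  best
}

# Deterministic restart list: the moment guess first, then perturbations.
fit_starts <- function(guess, model_kind, axis) {
  w <- axis$width_nm
  if (model_kind == "gaussian") {
    g <- guess
    list(g,
         replace(g, "sigma", g[["sigma"]] / 2),
         replace(g, "sigma", g[["sigma"]] * 2),
         replace(g, "mu", g[["mu"]] - w),
         replace(g, "mu", g[["mu"]] + w))
  } else {
    g <- gv_msq_from_raw(guess)
    list(g,
         replace(g, "q", max(g[["q"]] / 4, 1e-3)),
         replace(g, "s", g[["s"]] / 2),
         replace(g, "m", g[["m"]] - w),
         replace(g, "m", g[["m"]] + w))
  }
}

fit_once <- function(spectrum, ctr, span, axis, p0, model_kind, max_iterations) {
  n <- length(spectrum)
  if (model_kind == "gaussian") {
    lower <- c(1e-12, ctr[1L] - span, axis$width_nm / 10)
    upper <- c(Inf, ctr[n] + span, 10 * span)
    fn <- function(p) spectrum - p[1L] * exp(-(ctr - p[2L])^2 / (2 * p[3L]^2))
  } else {
    lower <- c(1e-12, ctr[1L] - span, axis$width_nm / 10, 1e-6)
    upper <- c(Inf, ctr[n] + span, 10 * span, 2)
    l0_max <- ctr[1L] - 1                       # onset stays blue of the window
    pen <- max(spectrum)
    fn <- function(p) {
      l0 <- p[2L] - p[3L] / p[4L]
      c(spectrum - gv_msq_eval(ctr, p), pen * max(l0 - l0_max, 0))
    }
  }
  p0 <- pmin(pmax(p0, lower), upper)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = as.integer(max_iterations),
                         ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  bad <- structure(list(model_kind = model_kind, params = NULL,
                        r_squared = NaN, converged = FALSE, n_points = n),
                   class = "fit_result")
  if (is.null(fit) || !fit$info %in% 1:4 || any(!is.finite(coef(fit))))
    return(bad)
  p <- coef(fit)
  if (model_kind == "gaussian") {
    params <- c(A = p[[1L]], mu = p[[2L]], sigma = p[[3L]])
    pred <- gaussian_model(ctr, params)
  } else {
    params <- gv_raw_from_msq(p)
    pred <- gv_msq_eval(ctr, p)
  }
  r2 <- r_squared(spectrum, pred)
  if (!is.finite(r2)) return(bad)
  structure(list(model_kind = model_kind, params = params,
                 r_squared = r2, converged = TRUE, n_points = n),
            class = "fit_result")
}

is_fit_result <- function(x) inherits(x, "fit_result")

#' @export
print.fit_result <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<fit_result> %s fit, R^2 = %.6f\n  %s\n", x$model_kind,
                x$r_squared,
                paste(sprintf("%s = %.6g", names(x$params), x$params),
                      collapse = ", ")))
  else
    cat(sprintf("<fit_result> %s fit: not converged\n", x$model_kind))
  invisible(x)
}

#' Evaluate a fitted spectral model at arbitrary wavelengths
#'
#' Continuous evaluation of the fitted curve — no 1 nm or channel-grid
#' rounding — used to read out the blue and red intensities for the GP
#' calculation. Always nonnegative.
#'
#' @param fit A converged [fit_spectrum()] result.
#' @param lambda_nm Wavelength(s) in nm.
#' @return Model intensity at each `lambda_nm`.
#' @export
evaluate_fit <- function(fit, lambda_nm) {
  stopifnot(is_fit_result(fit))
  if (!fit$converged)
    stop("cannot evaluate a non-converged fit")
  switch(fit$model_kind,
         gaussian = gaussian_model(lambda_nm, fit$params),
         gamma_variate = gamma_variate_model(lambda_nm, fit$params))
}
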