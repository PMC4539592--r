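# Shared fixtures, all built in code.

AX32 <- wavelength_axis(415, 8.9, 32)
CLAURDAN <- probe_preset("c-laurdan")

# a small deterministic stack: every pixel carries `spectrum`
uniform_stack <- function(spectrum, nr = 4, nc = 4, axis = AX32) {
  data <- array(rep(spectrum, each = nr * nc), c(nr, nc, length(spectrum)))
  spectral_stack(data, axis)
}

gauss_spec <- function(A, mu, sigma, axis = AX32)
  gaussian_model(axis$centers_nm, c(A = A, mu = mu, sigma = sigma))

gv_spec <- function(A, lambda0, alpha, beta, axis = AX32)
  gamma_variate_model(axis$centers_nm, c(A = A, lambda0 = lambda0,
                                         alpha = alpha, beta = beta))

# snap doubles to IEEE single precision (the storage format of float TIFFs)
as_float32 <- function(x) {
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
               n = length(x), size = 4L)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

# default two-phase reference scene, noiseless rendering
reference_render <- function(...) {
  scene <- make_two_phase_vesicle(...)
  list(scene = scene, render = render_stack(scene, noise = "none"))
}
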