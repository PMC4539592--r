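test_that("gp_value implements the normalized intensity contrast", {
  expect_equal(gp_value(10, 10), 0)
  expect_equal(gp_value(255, 0), 1)
  expect_equal(gp_value(1, 3), -0.5)
  expect_true(is.nan(gp_value(0, 0)))
  expect_error(gp_value(-1, 3), "nonnegative")
  # vectorized
  expect_equal(gp_value(c(1, 3), c(3, 1)), c(-0.5, 0.5))
})

test_that("division by 255 is value-neutral for the GP ratio", {
  set.seed(8)
  b <- runif(50) * 400
  r <- runif(50) * 400
  expect_equal(gp_value(b, r), (b - r) / (b + r))
})

test_that("direct sampling picks the nearest channel for each preset wavelength", {
  spec <- seq_len(32)          # spectrum = channel index, to read off picks
  ii <- direct_sample_intensities(spec, AX32, CLAURDAN)
  # brute-force argmin over |center - lambda|
  expect_equal(ii[["I_B"]], which.min(abs(AX32$centers_nm - 440)))
  expect_equal(ii[["I_R"]], which.min(abs(AX32$centers_nm - 490)))
  expect_equal(ii[["I_B"]], 3)    # center 437.25 nm
  expect_equal(ii[["I_R"]], 9)    # center 490.65 nm
  bad <- probe_preset("custom", lambda_lo = 300, lambda_ld = 490)
  expect_error(direct_sample_intensities(spec, AX32, bad), "outside")
})

test_that("built-in probe presets carry the published readout wavelengths", {
  cl <- probe_preset("c-laurdan")
  expect_equal(c(cl$lambda_lo, cl$lambda_ld), c(440, 490))
  di <- probe_preset("di-4-aneppdhq")
  expect_equal(c(di$lambda_lo, di$lambda_ld), c(565, 605))
  expect_error(probe_preset("custom"), "lambda_lo")
  expect_error(probe_preset("custom", lambda_lo = 440, lambda_ld = 440), "differ")
})

test_that("finite GP values always lie in [-1, 1]", {
  scene <- make_two_phase_vesicle(image_size = 48, peak_amplitude = 100)
  r <- render_stack(scene, noise = "poisson", seed = 2)
  for (method in c("direct", "gaussian")) {
    m <- compute_gp_map(r$stack, analysis_config(AX32, method = method))
    v <- m$gp[is.finite(m$gp)]
    expect_true(all(v >= -1 & v <= 1))
  }
})

test_that("GP maps are invariant under uniform stack scaling", {
  r <- reference_render(image_size = 32, ring_thickness = 4)
  stack <- r$render$stack
  scaled <- spectral_stack(stack$data * 7.3, stack$axis)
  for (method in c("direct", "gaussian")) {
    cfg <- analysis_config(AX32, method = method)
    m1 <- compute_gp_map(stack, cfg)
    m2 <- compute_gp_map(scaled, cfg)
    expect_equal(m2$gp, m1$gp, tolerance = 1e-9)
  }
})

test_that("swapping lambda_Lo and lambda_Ld negates every GP value", {
  r <- reference_render(image_size = 32, ring_thickness = 4)
  cfg <- analysis_config(AX32, method = "direct")
  swapped <- analysis_config(AX32, method = "direct",
                             preset = probe_preset("custom",
                                                   lambda_lo = 490, lambda_ld = 440))
  m1 <- compute_gp_map(r$render$stack, cfg)
  m2 <- compute_gp_map(r$render$stack, swapped)
  expect_equal(m2$gp, -m1$gp, tolerance = 1e-12)
})

test_that("GP decreases monotonically as the emission peak red-shifts", {
  mus <- seq(440, 490, by = 5)
  gps <- vapply(mus, function(mu) {
    ii <- direct_sample_intensities(gauss_spec(100, mu, 25), AX32, CLAURDAN)
    gp_value(ii[["I_B"]], ii[["I_R"]])
  }, numeric(1))
  expect_true(all(diff(gps) < 0))
  # and analytically, at the exact preset wavelengths
  gps_cont <- vapply(mus, function(mu)
    analytic_gp("gaussian", c(A = 1, mu = mu, sigma = 25), CLAURDAN), numeric(1))
  expect_true(all(diff(gps_cont) < 0))
})

test_that("per-phase pipeline GP matches the analytic oracles when noiseless", {
  r <- reference_render()
  lab <- r$render$truth$phase_label
  for (method in c("direct", "gaussian", "gamma_variate")) {
    m <- compute_gp_map(r$render$stack, analysis_config(AX32, method = method))
    for (i in seq_along(r$scene$phases)) {
      ph <- r$scene$phases[[i]]
      oracle <- analytic_gp(ph$model_kind, ph$params, CLAURDAN,
                            axis = if (method == "direct") AX32 else NULL)
      g <- m$gp[lab == i]
      g <- g[is.finite(g)]
      expect_gt(length(g), 500)
      expect_lt(max(abs(g - oracle)), 1e-3)
    }
  }
})

test_that("a maximal R^2 tolerance empties a noisy GP map", {
  scene <- make_two_phase_vesicle(image_size = 40, peak_amplitude = 100)
  r <- render_stack(scene, noise = "poisson", seed = 4)
  cfg <- analysis_config(AX32, method = "gaussian", r2_tolerance = 1.0)
  m <- compute_gp_map(r$stack, cfg)
  expect_lt(sum(is.finite(m$gp)), 3)    # noisy fits never reach R^2 = 1
  expect_gt(m$n_below_tolerance, 100)
})

test_that("an empty mask yields an all-NaN GP map with a warning", {
  s <- uniform_stack(rep(1, 32), nr = 4, nc = 4)   # constant projection -> all 0
  cfg <- analysis_config(AX32, method = "direct", background_subtraction = FALSE)
  expect_warning(m <- compute_gp_map(s, cfg), "empty")
  expect_true(all(is.nan(m$gp)))
})

test_that("histogram statistics split the positive and negative phases", {
  h <- gp_histogram(c(-0.4, -0.2, 0.1, 0.3, 0.5), bin_width = 0.02)
  expect_equal(h$median_negative, -0.3)
  expect_equal(h$median_positive, 0.3)
  expect_equal(h$n_pixels, 5)
  expect_equal(sum(h$counts), 5)
  expect_equal(h$median, 0.1)

  empty <- gp_histogram(c(NaN, NA), bin_width = 0.02)
  expect_equal(sum(empty$counts), 0)
  expect_true(is.nan(empty$mean) && is.nan(empty$median_positive))
})

test_that("histogram counts conserve the number of finite pixels", {
  set.seed(21)
  for (bw in c(0.02, 0.05, 0.3)) {
    v <- c(runif(200, -1, 1), NaN, NA, 1, -1)   # include both boundary values
    h <- gp_histogram(v, bin_width = bw)
    expect_equal(sum(h$counts), 202)
    expect_equal(h$n_pixels, 202)
  }
})

test_that("compare_methods reports one row per method and a per-phase table", {
  r <- reference_render(image_size = 48, ring_thickness = 4)
  cfg <- analysis_config(AX32)
  cmp <- compare_methods(r$render$stack, cfg, methods = c("direct", "gaussian"),
                         phase_label = r$render$truth$phase_label)
  expect_equal(nrow(cmp$summary), 2)
  expect_setequal(cmp$summary$method, c("direct", "gaussian"))
  expect_equal(nrow(cmp$per_phase), 4)        # 2 methods x 2 phases
  # noiseless single scene: methods agree on per-phase means within 1e-2
  # (direct carries its channel-discretization offset) and the fitted
  # method matches the continuous oracle to 1e-3
  ph1 <- subset(cmp$per_phase, phase == 1)
  expect_lt(abs(ph1$mean_gp[ph1$method == "gaussian"] - tanh(1)), 1e-3)
})
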