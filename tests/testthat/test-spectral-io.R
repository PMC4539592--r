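test_that("stack construction binds data to the axis and rejects mismatches", {
  ax <- wavelength_axis(415, 8.9, 32)
  s <- spectral_stack(array(1, c(4, 5, 32)), ax)
  expect_identical(dim(s), c(4L, 5L, 32L))
  expect_error(spectral_stack(array(1, c(4, 5, 31)), ax), "31.*32|channel")
  expect_error(spectral_stack(array(-1, c(4, 5, 32)), ax), "nonnegative")
})

test_that("float stack round-trips bit-exactly through TIFF", {
  ax <- wavelength_axis(415, 8.9, 8)
  set.seed(42)
  # arbitrary values round-trip bit-exactly at single precision ...
  data <- array(runif(6 * 7 * 8) * 1234.5, c(6, 7, 8))
  s <- spectral_stack(data, ax)
  path <- withr::local_tempfile(fileext = ".tif")
  write_spectral_stack(s, path)
  back <- read_spectral_stack(path, ax)
  expect_identical(back$data, as_float32(data))
  expect_identical(back$axis$centers_nm, ax$centers_nm)
  # ... and detector counts (exactly representable) round-trip identically
  counts <- array(as.numeric(rpois(6 * 7 * 8, 200)), c(6, 7, 8))
  write_spectral_stack(spectral_stack(counts, ax), path)
  expect_identical(read_spectral_stack(path, ax)$data, counts)
})

test_that("page-count mismatch on read names both counts", {
  ax8 <- wavelength_axis(415, 8.9, 8)
  ax7 <- wavelength_axis(415, 8.9, 7)
  s <- spectral_stack(array(1, c(4, 4, 8)), ax8)
  path <- withr::local_tempfile(fileext = ".tif")
  write_spectral_stack(s, path)
  expect_error(read_spectral_stack(path, ax7), "8 pages.*7 channels")
})

test_that("integer TIFF pages are promoted without rescaling", {
  ax <- wavelength_axis(415, 8.9, 3)
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- list(matrix(c(0, 100, 30, 255) / 255, 2, 2),
                matrix(c(1, 2, 3, 4) / 255, 2, 2),
                matrix(0, 2, 2))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  s <- read_spectral_stack(path, ax)
  expect_equal(s$data[, , 1], matrix(c(0, 100, 30, 255), 2, 2))
  expect_equal(s$data[, , 2], matrix(1:4, 2, 2))
})

test_that("negative intensities are clipped to zero with a warning on load", {
  ax <- wavelength_axis(415, 8.9, 3)
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- list(matrix(c(-0.5, 2, 3, 4), 2, 2), matrix(1, 2, 2), matrix(1, 2, 2))
  spectralGP:::write_float_tiff(pages, path)
  expect_warning(s <- read_spectral_stack(path, ax), "clipped")
  expect_equal(s$data[1, 1, 1], 0)
  expect_equal(s$data[2, 1, 1], 2)
})

test_that("wavelength axis can be recovered from OME channel metadata", {
  skip_if_not_installed("xml2")
  # synthetic OME description: 4 channels on a uniform 10 nm grid from 425
  desc <- paste0(
    '<?xml version="1.0"?><OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image><Pixels>',
    paste0('<Channel ID="Channel:', 0:3, '" EmissionWavelength="',
           c(425, 435, 445, 455), '"/>', collapse = ""),
    '</Pixels></Image></OME>')
  ax <- spectralGP:::axis_from_ome_description(desc, "x.tif")
  expect_equal(ax$n_channels, 4L)
  expect_equal(ax$centers_nm, c(425, 435, 445, 455))
  expect_equal(ax$width_nm, 10)
  expect_error(spectralGP:::axis_from_ome_description("", "x.tif"),
               "explicit wavelength_axis")
})

test_that("sensitivity correction scales channels componentwise", {
  ax <- wavelength_axis(415, 8.9, 4)
  s <- spectral_stack(array(rep(c(1, 2, 3, 4), each = 6), c(2, 3, 4)), ax)
  ident <- apply_sensitivity_correction(s, rep(1, 4))
  expect_identical(ident$data, s$data)
  corr <- apply_sensitivity_correction(s, c(2, 1, 1, 1))
  expect_equal(corr$data[, , 1], s$data[, , 1] * 2)
  expect_identical(corr$data[, , 2:4], s$data[, , 2:4])
  expect_error(apply_sensitivity_correction(s, rep(1, 3)), "3 factors")
  expect_error(apply_sensitivity_correction(s, c(0, 1, 1, 1)), "> 0")
})

test_that("uniform sensitivity correction leaves every GP value unchanged", {
  r <- reference_render(image_size = 32, ring_thickness = 4)
  cfg <- analysis_config(AX32, method = "direct")
  base <- compute_gp_map(r$render$stack, cfg)
  cfg2 <- analysis_config(AX32, method = "direct",
                          sensitivity_correction = rep(3.7, 32))
  scaled <- compute_gp_map(r$render$stack, cfg2)
  expect_equal(scaled$gp, base$gp, tolerance = 1e-12)
})

test_that("write_gp_outputs produces the documented file set", {
  r <- reference_render(image_size = 32, ring_thickness = 4)
  cfg <- analysis_config(AX32, method = "gaussian")
  gpmap <- compute_gp_map(r$render$stack, cfg)
  out <- withr::local_tempdir()
  paths <- write_gp_outputs(gpmap, out)
  expect_true(all(file.exists(paths)))
  expect_setequal(names(paths), c("gp", "lut", "mask", "histogram", "summary", "r2"))

  # float GP TIFF round-trips bitwise at single precision, NaN for excluded
  gp_back <- read_float_image(paths[["gp"]])
  expect_identical(gp_back, as_float32(gpmap$gp))
  expect_identical(is.nan(gp_back), !is.finite(gpmap$gp))

  # mask is 0/255 8-bit
  mask_back <- tiff::readTIFF(paths[["mask"]], as.is = TRUE)
  expect_setequal(unique(as.vector(mask_back)), c(0, 255))
  expect_equal(mask_back == 255, gpmap$mask$include)

  # histogram counts total the finite pixels
  h <- read.csv(paths[["histogram"]])
  expect_named(h, c("bin_left", "bin_right", "count"))
  expect_equal(sum(h$count), sum(is.finite(gpmap$gp)))
  s <- read.csv(paths[["summary"]])
  expect_equal(s$n_pixels, sum(is.finite(gpmap$gp)))
})

test_that("an all-masked GP map writes an all-NaN TIFF and an empty histogram", {
  ax <- wavelength_axis(415, 8.9, 4)
  gpmap <- structure(list(gp = array(NaN, c(2, 2)), r2 = NULL,
                          mask = compute_mask(matrix(0, 2, 2), 10L),
                          method = "direct", preset = CLAURDAN, axis = ax,
                          background = NULL, n_fit_failures = 0L,
                          n_below_tolerance = 0L),
                     class = "gp_map")
  out <- withr::local_tempdir()
  paths <- write_gp_outputs(gpmap, out)
  expect_true(all(is.nan(read_float_image(paths[["gp"]]))))
  h <- read.csv(paths[["histogram"]])
  expect_named(h, c("bin_left", "bin_right", "count"))
  expect_equal(sum(h$count), 0)
})

test_that("a 2x2 half-finite GP map counts two histogram pixels", {
  ax <- wavelength_axis(415, 8.9, 4)
  gpmap <- structure(list(gp = matrix(c(0.5, -0.5, NaN, NaN), 2, 2), r2 = NULL,
                          mask = compute_mask(matrix(c(255, 255, 0, 0), 2, 2), 10L),
                          method = "direct", preset = CLAURDAN, axis = ax,
                          background = NULL, n_fit_failures = 0L,
                          n_below_tolerance = 0L),
                     class = "gp_map")
  out <- withr::local_tempdir()
  paths <- write_gp_outputs(gpmap, out)
  expect_equal(sum(read.csv(paths[["histogram"]])$count), 2)
})
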