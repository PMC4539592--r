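# Orchestration: config files and full runs.

#' Build an analysis configuration from a plain list (YAML/JSON)
#'
#' Accepts the keys written by [write_run_manifest()] / the CLI config file:
#' `axis: {start_nm, width_nm, n_channels}`, `probe` (preset name),
#' `lambda_lo`, `lambda_ld`, `method`, `mask_threshold`,
#' `background_subtraction`, `background_statistic`, `r2_tolerance`,
#' `bin_width`, `sensitivity_correction`, `max_iterations`. Missing keys
#' fall back to the [analysis_config()] defaults.
#'
#' @param x Named list, e.g. from `yaml::read_yaml()`.
#' @return An [analysis_config()].
#' @export
as_analysis_config <- function(x) {
  stopifnot(is.list(x))
  if (is.null(x$axis) || !all(c("start_nm", "width_nm", "n_channels") %in% names(x$axis)))
    stop("config must contain axis: {start_nm, width_nm, n_channels}")
  axis <- wavelength_axis(x$axis$start_nm, x$axis$width_nm, x$axis$n_channels)
  preset <- probe_preset(x$probe %||% "c-laurdan",
                         lambda_lo = x$lambda_lo, lambda_ld = x$lambda_ld)
  args <- list(axis = axis, preset = preset)
  for (key in c("method", "mask_threshold", "background_subtraction",
                "background_statistic", "r2_tolerance", "bin_width",
                "sensitivity_correction", "max_iterations"))
    if (!is.null(x[[key]])) args[[key]] <- x[[key]]
  do.call(analysis_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file with the keys of [as_analysis_config()].
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  as_analysis_config(yaml::read_yaml(path))
}

config_as_list <- function(config) {
  list(axis = list(start_nm = config$axis$start_nm,
                   width_nm = config$axis$width_nm,
                   n_channels = config$axis$n_channels),
       probe = config$preset$name,
       lambda_lo = config$preset$lambda_lo,
       lambda_ld = config$preset$lambda_ld,
       method = config$method,
       mask_threshold = config$mask_threshold,
       background_subtraction = config$background_subtraction,
       background_statistic = config$background_statistic,
       r2_tolerance = config$r2_tolerance,
       bin_width = config$bin_width,
       sensitivity_correction = config$sensitivity_correction,
       max_iterations = config$max_iterations)
}

#' Run a complete GP analysis and write all artifacts
#'
#' Validates the configuration, loads the stack (unless one is passed
#' directly), computes the GP map, writes the standard output set
#' ([write_gp_outputs()]) and a machine-readable `manifest.json` recording
#' the full configuration, package version, input, seed and failure counts,
#' so every output directory is self-describing and the run reproducible.
#' Nothing is written if validation or loading fails. Identical
#' configuration and input give bit-identical GP map files.
#'
#' @param input Path to a multi-page spectral TIFF, or a [spectral_stack()].
#' @param config An [analysis_config()].
#' @param out_dir Output directory.
#' @param seed Optional integer recorded in the manifest (the analysis
#'   itself is deterministic; the seed documents upstream simulation runs).
#' @return The [compute_gp_map()] result, invisibly.
#' @export
run_gp_analysis <- function(input, config, out_dir, seed = NULL) {
  stopifnot(is_analysis_config(config))
  stack <- if (is_spectral_stack(input)) input
           else read_spectral_stack(input, config$axis)
  gpmap <- compute_gp_map(stack, config)
  paths <- write_gp_outputs(gpmap, out_dir, config$bin_width)
  write_run_manifest(file.path(out_dir, "manifest.json"), config,
                     source = stack$source, seed = seed, gpmap = gpmap,
                     files = basename(paths))
  invisible(gpmap)
}

write_run_manifest <- function(path, config, source, seed, gpmap, files) {
  manifest <- list(
    package = "spectralGP",
    version = as.character(utils::packageVersion("spectralGP")),
    input = source,
    seed = seed,
    config = config_as_list(config),
    n_fit_failures = gpmap$n_fit_failures,
    n_below_tolerance = gpmap$n_below_tolerance,
    n_masked_pixels = sum(gpmap$mask$include),
    n_finite_gp = sum(is.finite(gpmap$gp)),
    files = as.list(files))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
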