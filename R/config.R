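#' Default pipeline configuration
#'
#' Returns the full parameter set of the analysis chain, grouped by stage.
#' Where the device's published protocol states a value (90 Hz, 125 lux,
#' 3 cycles, 1/9 mm cutoffs, 90-sample gap limit, 100-sample smoothing
#' window) that value is the default; the remaining parameters are the
#' package's documented choices.
#'
#' @return A nested named list with `timeline`, `preprocess`, `reflex` and
#'   `diagnostics` blocks; round-trips losslessly through YAML or JSON via
#'   [write_config()] / [read_config()].
#' @export
default_config <- function() {
  list(
    timeline = list(sample_rate_hz = 90, intensity_lux = 125, n_cycles = 3,
                    cycle_order = "alternating", pulse_duration_s = 1,
                    dark_duration_s = 3, adaptation_s = 5),
    preprocess = list(lo_mm = 1, hi_mm = 9, max_gap_samples = 90,
                      window_samples = 100, published_order = FALSE),
    reflex = list(baseline_window_s = 0.5, response_window_s = 2.5,
                  baseline_mode = "adaptation", baseline_margin_s = NULL,
                  efferent_ratio = 1.25, aggregate = "mean"),
    diagnostics = list(quantile = 0.25, seed = 1)
  )
}

# overlay user values onto the defaults, block by block
merge_config <- function(user) {
  cfg <- default_config()
  for (block in intersect(names(user), names(cfg))) {
    for (key in intersect(names(user[[block]]), names(cfg[[block]]))) {
      cfg[[block]][[key]] <- user[[block]][[key]]
    }
  }
  cfg
}

#' Read or write a pipeline configuration file
#'
#' Format is chosen by extension: `.yml`/`.yaml` or `.json`. Reading
#' overlays the file's values onto [default_config()], so partial configs
#' are valid.
#'
#' @param path File path.
#' @return For `read_config()`, the merged configuration list; for
#'   `write_config()`, `path` invisibly.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
                 yml = , yaml = yaml::read_yaml(path),
                 json = jsonlite::read_json(path, simplifyVector = TRUE),
                 stop("unsupported config format: .", ext, call. = FALSE))
  merge_config(user)
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yml = , yaml = yaml::write_yaml(config, path),
         json = jsonlite::write_json(config, path, auto_unbox = TRUE,
                                     pretty = TRUE, digits = NA),
         stop("unsupported config format: .", ext, call. = FALSE))
  invisible(path)
}
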