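#' Analysis configuration
#'
#' Every tunable numeric parameter of the pipeline, with the published
#' acquisition-device values as defaults (image resolution 1360 x 1024 px,
#' Keratograph-class optics). The configuration round-trips losslessly
#' through YAML via [read_config()] / [write_config()].
#'
#' @param ... named overrides in `section.name = value` form is not
#'   supported; pass nested lists, e.g. `mg_config(roi = list(erode_radius
#'   = 8))` to override single entries (unnamed sections keep defaults).
#' @return A nested list of class `mg_config`.
#' @export
mg_config <- function(...) {
  defaults <- list(
    mm_per_px = 0.02,
    roi = list(
      split_smooth_rows = 31L,
      split_peak_margin = 10,
      erode_radius = 10L,
      sharpen_sigma = 30,
      sharpen_amount = 1,
      median_size = 40L,
      min_edge_px = 500L,
      min_obj_px = 500L,
      entropy_radius = 4L,
      peak_frac = 0.5,
      sd_radius = 4L,
      chan_vese_iterations = 60L,
      chan_vese_tol = 0.001,
      chan_vese_max_displacement = 25L
    ),
    segmentation = list(
      sigma_low = 2,
      sigma_high = 30,
      sensitivity = 0.7,
      adaptive_window = 75L,
      rim_px = 5L,
      min_gland_px = 800L,
      orientation_min = 40,
      orientation_max = 140
    ),
    fragmentation = list(
      NlTH = 1L, OTH = 50, NoTH = 1L, O2TH = 50, RTH = 3,
      min_prominence_frac = 0.2
    ),
    morphometrics = list(
      disk_radius = 20L,
      reflection_threshold = 200,
      gland_region_method = "closing"   # or "meanfilter"
    )
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(defaults))
      parameter_error(sprintf("unknown config section: %s", nm))
    if (is.list(defaults[[nm]])) {
      for (k in names(over[[nm]])) {
        if (!k %in% names(defaults[[nm]]))
          parameter_error(sprintf("unknown config entry: %s.%s", nm, k))
        defaults[[nm]][[k]] <- over[[nm]][[k]]
      }
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  structure(defaults, class = "mg_config")
}

#' @rdname mg_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    file_not_found_error(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  do.call(mg_config, raw)
}

#' @rdname mg_config
#' @param config an `mg_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Short provenance hash of a configuration.
config_hash <- function(config) {
  rlang::hash(unclass(config))
}
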