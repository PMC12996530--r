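#' Read and validate a run configuration
#'
#' A single hierarchical YAML document configures a reproducible end-to-end
#' run. Known top-level sections are `seed` (required), `paths`, `geometry`,
#' `simulate`, `noise`, `preprocess`, `model`, `train`, `threshold` and
#' `crlb`; unknown keys are rejected so typos fail loudly rather than being
#' silently ignored.
#'
#' @param path Path to a YAML file.
#' @return The validated configuration as a named list, class
#'   `nsm_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Config file not found: %s", path),
                 class = "nanokymo_config_error")
  }
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "paths", "geometry", "simulate", "noise", "preprocess",
             "model", "train", "threshold", "crlb")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    rlang::abort(sprintf("Unknown config key(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "nanokymo_config_error")
  }
  if (is.null(cfg$seed) || !is.numeric(cfg$seed)) {
    rlang::abort("Config must set an integer `seed` for reproducibility.",
                 class = "nanokymo_config_error")
  }
  structure(cfg, class = "nsm_run_config")
}

#' Build a channel geometry from a config section
#' @param section Named list with `width_nm`, `depth_nm` and optionally
#'   `pixel_size_nm`, `n_pixels`, `area_nm2`.
#' @return A [channel_geometry()].
#' @export
geometry_from_config <- function(section) {
  channel_geometry(
    width_nm = section$width_nm, depth_nm = section$depth_nm,
    pixel_size_nm = section$pixel_size_nm %||% 27.4,
    n_pixels = section$n_pixels %||% 512L,
    area_nm2 = section$area_nm2
  )
}
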