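# Nested run configuration with validated keys and documented defaults,
# loadable from YAML.  Unknown keys are rejected rather than silently
# ignored.

run_config_defaults <- function() {
  list(
    gaussian = list(size = 5L, sigma = 1.0, normalize = TRUE),
    edge = list(threshold = "otsu"),
    template = list(radius = 8L, variant = "gray_boundary",
                    gray_weight = 0.5, exclusion_radius = NULL,
                    floor_score = 0.2),
    stage = list(sigma_move_um = 0.3, rel_sigma = 5e-4,
                 pitch_bias = 0.002, drift_um = c(25, 18)),
    alignment = list(tolerance = 3, max_iterations = 5L,
                     update_distances = TRUE, capture_noise_sd = 5),
    render = list(size = 301L, background = 200, radius = 8,
                  ring_width = 3, spacing = 40, ring_intensity = 60,
                  noise_sd = 5),
    geometry = list(rows = 4L, cols = 8L, pitch_x = 3000, pitch_y = 3000,
                    mark_to_chamber = c(1200, 1200), pixel_width = 0.94,
                    frame_px = 301L),
    seed = 1L
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults))
      stop("unknown config key: ", key, call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("config key ", key, " must be a mapping", call. = FALSE)
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], key)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML file of pipeline / simulator parameters and merges it
#' over the documented defaults; unknown keys raise an error.  With
#' `path = NULL` the defaults are returned.
#'
#' @param path YAML file or NULL.
#' @return A `run_config` nested list with sections `gaussian`, `edge`,
#'   `template`, `stage`, `alignment`, `render`, `geometry`, `seed`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config file must be a YAML mapping",
                             call. = FALSE)
    cfg <- merge_config(cfg, user)
  }
  structure(cfg, class = "run_config")
}

# Build the typed parameter objects from a run_config.
config_detect <- function(cfg) {
  detect_config(gaussian_size = cfg$gaussian$size,
                gaussian_sigma = cfg$gaussian$sigma,
                gaussian_normalize = cfg$gaussian$normalize,
                edge_threshold = cfg$edge$threshold,
                template_radius = cfg$template$radius,
                template_variant = cfg$template$variant,
                template_gray = cfg$template$gray_weight,
                exclusion_radius = cfg$template$exclusion_radius,
                floor_score = cfg$template$floor_score)
}

config_alignment <- function(cfg) {
  alignment_config(tolerance = cfg$alignment$tolerance,
                   max_iterations = cfg$alignment$max_iterations,
                   update_distances = cfg$alignment$update_distances,
                   detect = config_detect(cfg),
                   capture_noise_sd = cfg$alignment$capture_noise_sd)
}

config_geometry <- function(cfg) {
  device_geometry(rows = cfg$geometry$rows, cols = cfg$geometry$cols,
                  pitch_x = cfg$geometry$pitch_x,
                  pitch_y = cfg$geometry$pitch_y,
                  mark_to_chamber = cfg$geometry$mark_to_chamber,
                  pixel_width = cfg$geometry$pixel_width,
                  mark_radius_px = cfg$render$radius,
                  mark_spacing_px = cfg$render$spacing,
                  frame_px = cfg$geometry$frame_px)
}
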