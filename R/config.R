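# Pipeline configuration: schema-validated parameters with preset
# defaults, loadable from YAML or JSON.

config_schema <- function() {
  num <- function(min = -Inf, max = Inf) list(type = "numeric", min = min, max = max)
  list(
    preset        = list(type = "character", values = c("day5", "day20", "custom")),
    strict        = list(type = "logical"),
    write_images  = list(type = "logical"),
    n_runs        = num(1, 100),
    n_strips      = num(1, 100),
    pixel_pitch_um = num(1e-3, 100),
    noise_sd      = num(0, 0.5),
    initial_gap_um = num(0, 1000),
    search_radius = num(1, 100),
    score_floor   = num(-1, 1),
    poisson_ratio = num(0, 0.5),
    spring_constant = num(1e-6, 1e3),
    volts_per_step = num(1e-3, 100),
    max_volts     = num(1e-3, 1000),
    gain_um_per_v = num(1e-3, 100),
    diameter_um   = num(1, 5000),
    youngs_modulus_pa = num(0, 1e6),
    panel_width_um = num(1, 5000),
    overlap_frac  = num(0, 0.9),
    resolution    = num(0.1, 64),
    strip_length_um = num(10, 5000),
    strip_height_um = num(10, 1000)
  )
}

#' Default pipeline configuration
#'
#' All parameters of both pipeline arms with the defaults implied by the
#' chosen preset (instrument constants, presets for spheroid and TEM
#' statistics, raster and tracking settings).
#'
#' @param preset `"day5"`, `"day20"` or `"custom"`.
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function(preset = "day5") {
  sph <- if (preset %in% c("day5", "day20")) spheroid_preset(preset)
         else spheroid_spec(425, 500)
  tp <- tem_preset(if (preset == "day20") "day20" else "day5")
  structure(list(
    preset = preset, strict = FALSE, write_images = FALSE,
    n_runs = 6, n_strips = 3,
    pixel_pitch_um = 2, noise_sd = 0.02, initial_gap_um = 40,
    search_radius = 6, score_floor = 0.5, poisson_ratio = 0.5,
    spring_constant = cantilever_spring_constant(cantilever_preset()),
    volts_per_step = 1.1, max_volts = 40, gain_um_per_v = 4.9 / 1.1,
    diameter_um = sph$diameter_um, youngs_modulus_pa = sph$youngs_modulus_pa,
    panel_width_um = 60, overlap_frac = 0.10, resolution = 2,
    strip_length_um = tp$strip_length_um,
    strip_height_um = tp$strip_height_um
  ), class = "pipeline_config")
}

validate_config <- function(cfg) {
  schema <- config_schema()
  problems <- character(0)
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    problems <- c(problems, paste("unknown key(s):",
                                  paste(unknown, collapse = ", ")))
  for (key in intersect(names(cfg), names(schema))) {
    sc <- schema[[key]]; val <- cfg[[key]]
    if (sc$type == "numeric") {
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
        problems <- c(problems, sprintf("'%s' must be a single number", key))
      else if (val < sc$min || val > sc$max)
        problems <- c(problems, sprintf("'%s' = %g outside [%g, %g]",
                                        key, val, sc$min, sc$max))
    } else if (sc$type == "logical") {
      if (!is.logical(val) || length(val) != 1L || is.na(val))
        problems <- c(problems, sprintf("'%s' must be TRUE or FALSE", key))
    } else if (sc$type == "character") {
      if (!is.character(val) || length(val) != 1L || !(val %in% sc$values))
        problems <- c(problems, sprintf("'%s' must be one of: %s", key,
                                        paste(sc$values, collapse = ", ")))
    }
  }
  abort_if(length(problems) > 0,
           paste0("invalid configuration:\n  ",
                  paste(problems, collapse = "\n  ")))
  invisible(cfg)
}

#' Load a pipeline configuration file
#'
#' Reads a YAML or JSON file, overlays it on the preset defaults, and
#' validates every key against the schema (unknown keys and
#' out-of-range values are rejected, all violations listed at once).
#' An empty file yields the preset defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   pure defaults.
#' @param preset Preset supplying defaults (overridden by a `preset` key
#'   in the file).
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path = NULL, preset = "day5") {
  user <- list()
  if (!is.null(path)) {
    abort_if(!file.exists(path), sprintf("config file not found: %s", path))
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()  # empty file
  }
  if (!is.null(user$preset)) preset <- user$preset
  cfg <- default_config(preset)
  for (key in names(user)) cfg[[key]] <- user[[key]]
  validate_config(cfg)
  cfg
}

#' Write the effective configuration next to the outputs
#'
#' @param cfg A `pipeline_config`.
#' @param path YAML output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}
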