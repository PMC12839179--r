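# Pipeline configuration: one nested list, round-tripped through YAML.

#' Default pipeline configuration
#'
#' All physical quantities in SI units; every random draw in the pipeline
#' descends from the single `gait$seed` through named substreams.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(
    list(
      subject = list(mass = 87.6, height = 1.86),
      gait = list(speed = 1.25, stance_duration = 0.65, noise_sd = 0.005,
                  n_contacts = 10L, n_samples = 100L, seed = 1L),
      exo = list(
        shank_attach_r = 0.30, foot_attach_r = 0.15,
        attach_offset_angle = 1.75,
        bracket_mass_foot = 1.2, bracket_mass_shank = 0.8,
        mass_lever_foot = 0.18, mass_lever_shank = 0.06
      ),
      grid = list(k_min = 5500, k_max = 17500, k_step = 500,
                  tau_min = 15, tau_max = 60, tau_step = 5),
      solver = list(reserve_weight = 1e3, reserve_threshold = 1.0),
      conditions = list(s1 = c(5500, 15), s2 = c(12000, 25)),
      output_dir = "exosweep-out"
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in names(user)) {
    if (is.list(cfg[[section]])) {
      for (field in names(user[[section]])) {
        cfg[[section]][[field]] <- user[[section]][[field]]
      }
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  validate_config(cfg)
}

#' Write a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  pos <- c(
    cfg$subject$mass, cfg$subject$height, cfg$gait$speed,
    cfg$gait$stance_duration, cfg$exo$shank_attach_r, cfg$exo$foot_attach_r,
    cfg$grid$k_min, cfg$grid$k_step, cfg$grid$tau_step,
    cfg$solver$reserve_weight
  )
  if (any(pos <= 0)) stop_invalid("config physical quantities must be positive")
  if (cfg$gait$noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  class(cfg) <- "pipeline_config"
  cfg
}

config_geometry <- function(cfg) {
  do.call(exo_geometry, cfg$exo)
}

config_cohort <- function(cfg) {
  generate_cohort(
    n_contacts = cfg$gait$n_contacts, speed = cfg$gait$speed,
    stance_duration = cfg$gait$stance_duration,
    subject_mass = cfg$subject$mass, subject_height = cfg$subject$height,
    noise_sd = cfg$gait$noise_sd, seed = cfg$gait$seed,
    n_samples = cfg$gait$n_samples
  )
}
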