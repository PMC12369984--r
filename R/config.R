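#' Default run configuration
#'
#' One structured document with sections for the simulator, the kinetics
#' calibration, the step model, the continuum solver, the analysis options
#' and the pore-size module. Units are hours and micrometers, except
#' `steps$frame_interval_min` (minutes, converted on use). The single `seed`
#' governs all stochastic stages through a fixed per-stage derivation rule
#' (simulation uses `seed`; report cohorts use `seed + 100 + i`; synthetic
#' fiber images use `seed + 200`), so each stage is individually
#' reproducible.
#'
#' @return Nested list of defaults (see [read_run_config()] for validation).
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "mesoinvasion-output",
    simulation = list(
      spheroid_radius = 200, duration = 24, release_flux = 15,
      n_initial_cells = 0, label_noise_intermediate = 0,
      tangential_sd = 0, schedule_on = FALSE),
    schedule = list(
      zone_width = 50, t_start = 8, t_end = 24, target = "FP",
      continuous_ramp = FALSE, direction = "into"),
    rates = list(
      file = NULL,
      fractions = list(BB = 1/3, AE = 1/6, LA = 1/4, FP = 1/4),
      mean_transition_interval = 2),
    steps = list(
      mean = list(BB = 1.7, AE = 2.8, LA = 1.8, FP = 4.5),
      sd = list(BB = 4.2, AE = 3.5, LA = 5.2, FP = 5.9),
      frame_interval_min = 15),
    continuum = list(
      flux = 4, dr = 5, dt = NULL, r_max_offset = 1000, duration = 24,
      diffusion = "none"),
    analysis = list(
      zone = 50, bin_width = 50, depletion_window = 4,
      enrichment_window = 4, max_lag = 10),
    pore = list(
      pixel_size = 1, threshold = "otsu", fiber = "bright", min_area = 4,
      n_fibers = 40, fiber_width = 3, size = 256)
  )
}

# recursive unknown-key check; `path` accumulates the YAML path for messages
check_config_keys <- function(cfg, ref, path = "") {
  if (!is.list(cfg)) return(invisible(TRUE))
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown configuration key", if (length(extra) > 1) "s", ": ",
         paste0(sub("^/", "", paste0(path, "/", extra)), collapse = ", "),
         call. = FALSE)
  for (k in names(cfg))
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, "/", k))
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]]) &&
        !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read and validate a run configuration file
#'
#' YAML document with the sections of [default_run_config()]; unknown keys
#' are rejected with the offending key path, and given values are merged
#' over the defaults.
#'
#' @param path YAML file path, or `NULL` for the pure defaults.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- default_run_config()
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  check_config_keys(cfg, defaults)
  validate_run_config(merge_config(defaults, cfg))
}

#' @rdname read_run_config
#' @param config Configuration list to write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  with(cfg$simulation, stopifnot(spheroid_radius > 0, duration > 0,
                                 release_flux >= 0, n_initial_cells >= 0))
  stopifnot(cfg$continuum$diffusion %in% c("none", "steps"))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

config_rates <- function(cfg) {
  if (!is.null(cfg$rates$file)) return(read_rate_matrix(cfg$rates$file))
  calibrate_default_rates(unlist(cfg$rates$fractions),
                          cfg$rates$mean_transition_interval)
}

config_schedule <- function(cfg) {
  if (!isTRUE(cfg$simulation$schedule_on)) return(NULL)
  s <- cfg$schedule
  modulation_schedule(zone_width = s$zone_width, t_start = s$t_start,
                      t_end = s$t_end, target = s$target,
                      continuous_ramp = s$continuous_ramp,
                      direction = s$direction)
}

config_steps <- function(cfg) {
  step_model(mean = unlist(cfg$steps$mean), sd = unlist(cfg$steps$sd),
             frame_interval = cfg$steps$frame_interval_min / 60)
}

config_simulation <- function(cfg, seed = cfg$seed) {
  s <- cfg$simulation
  simulation_config(spheroid_radius = s$spheroid_radius,
                    duration = s$duration, release_flux = s$release_flux,
                    n_initial_cells = s$n_initial_cells,
                    rates = config_rates(cfg), steps = config_steps(cfg),
                    schedule = config_schedule(cfg),
                    label_noise_intermediate = s$label_noise_intermediate,
                    tangential_sd = s$tangential_sd, seed = seed)
}

config_continuum <- function(cfg) {
  steps <- config_steps(cfg)
  continuum_params(
    rates = config_rates(cfg), speeds = step_speeds(steps),
    flux = cfg$continuum$flux, schedule = config_schedule(cfg),
    diffusion = if (cfg$continuum$diffusion == "steps")
      step_diffusivities(steps) else 0,
    r_s = cfg$simulation$spheroid_radius,
    r_max = cfg$simulation$spheroid_radius + cfg$continuum$r_max_offset,
    dr = cfg$continuum$dr, dt = cfg$continuum$dt,
    duration = cfg$continuum$duration)
}
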