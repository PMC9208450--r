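SNAPSHOT_VERSION <- 1L

# config fields that fully determine a run (plain scalars/vectors only)
serialize_config <- function(config) {
  list(duration = config$duration, dt = config$dt,
       snapshot_interval = config$snapshot_interval,
       muscle_strength = config$muscle_strength, sensor = config$sensor,
       apg = unclass(config$apg), plant = unclass(config$plant),
       gains = config$gains, leak_gain = config$leak_gain,
       hp_cutoff = config$hp_cutoff, eta_exponent = config$eta_exponent,
       eta_scale = config$eta_scale, eta_max = config$eta_max,
       init_mean = config$init_mean, init_sd = config$init_sd,
       init_floor = config$init_floor, learn = config$learn)
}

deserialize_config <- function(x) {
  apg <- do.call(apg_config, x$apg[c("variant", "p", "duration_range",
                                     "gain_range", "epoch")])
  plant <- do.call(plant_params,
                   x$plant[c("damping", "muscle_strength", "gain",
                             "stiction_fraction", "limb_limit", "wall_left",
                             "wall_right", "limb_offset", "dt")])
  sim_config(duration = x$duration, dt = x$dt,
             snapshot_interval = x$snapshot_interval,
             muscle_strength = x$muscle_strength, sensor = x$sensor,
             apg = apg, plant = plant,
             gains = x$gains, leak_gain = x$leak_gain,
             hp_cutoff = x$hp_cutoff, eta_exponent = x$eta_exponent,
             eta_scale = x$eta_scale, eta_max = x$eta_max,
             init_mean = x$init_mean, init_sd = x$init_sd,
             init_floor = x$init_floor, learn = x$learn)
}

#' Write a simulation snapshot
#'
#' Serializes the complete network and plant state of a run (all weights,
#' traces, positions), together with the seed and configuration, as JSON at
#' full double precision. A snapshot can be reloaded with
#' [read_snapshot()] and resumed with [resume_simulation()]; the resumed
#' trajectory is bit-identical to an unbroken run.
#'
#' @param sim a `spinloop_sim` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(sim, path) {
  obj <- list(format = "spinloop-snapshot", version = SNAPSHOT_VERSION,
              package_version = as.character(utils::packageVersion("spinloop")),
              seed = sim$seed, step = sim$n_steps,
              config = serialize_config(sim$config), state = sim$state)
  # 17 significant digits: doubles round-trip bit-exactly through the file
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a simulation snapshot
#'
#' @param path a file written by [write_snapshot()].
#' @return list with `seed`, `step`, `config` (a [sim_config()]) and
#'   `state`.
#' @export
read_snapshot <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse snapshot file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, "spinloop-snapshot")) {
    stop("not a spinloop snapshot file", call. = FALSE)
  }
  if (!identical(as.integer(obj$version), SNAPSHOT_VERSION)) {
    stop("snapshot version ", obj$version, " not supported (expected ",
         SNAPSHOT_VERSION, ")", call. = FALSE)
  }
  list(seed = obj$seed, step = obj$step,
       config = deserialize_config(obj$config),
       state = lapply(obj$state, as.numeric))
}

#' Resume a run from a snapshot
#'
#' Re-derives the twitch stream from the stored seed, fast-forwards to the
#' snapshot step and continues the simulation to the configured duration.
#' Determinism of the generator makes the result identical to a run that
#' was never interrupted.
#'
#' @param snapshot a file path or the result of [read_snapshot()].
#' @param duration optional new total duration in seconds (to continue a
#'   finished run further); default: the stored configuration's duration.
#' @return a `spinloop_sim` covering the full configured duration.
#' @export
resume_simulation <- function(snapshot, duration = NULL) {
  if (is.character(snapshot)) snapshot <- read_snapshot(snapshot)
  cfg <- snapshot$config
  if (!is.null(duration)) cfg$duration <- duration
  run_simulation(cfg, seed = as.integer(snapshot$seed),
                 state = snapshot$state,
                 start_step = as.integer(snapshot$step))
}
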