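# shared fixtures: a unit-gain plant (G*MS = 1) for algebraic force checks,
# and short-run configs for engine tests

unit_plant <- function(ms = 1) {
  plant_params(gain = 1, muscle_strength = ms)
}

short_config <- function(duration = 100, ...) {
  sim_config(duration = duration, snapshot_interval = 0, ...)
}

# four muscle names in canonical order, used for trace columns
A_COLS <- paste0("A_", MUSCLES)
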