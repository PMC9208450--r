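#' Activity pattern generator configuration
#'
#' The APG stands in for spontaneous fetal motor drive: randomized twitch
#' pulses injected into each motoneuron through a fixed, non-learnable
#' synapse of weight 1. Once per decision epoch, each idle motoneuron
#' independently starts a twitch with probability `p`; reduced variants
#' restrict which combinations can occur.
#'
#' @param variant `"full"` (independent twitches), `"no_cocontraction"`
#'   (a twitch is cancelled if the same-limb antagonist is active at its
#'   onset), `"symmetrical_only"` (joint twitches for the mirror pairs
#'   LE+RE or LF+RF), `"in_phase_only"` (joint twitches for the
#'   contralateral synergist pairs LE+RF or LF+RE), or `"phasic"`
#'   (scripted schedules; see [phasic_sequence()]).
#' @param p per-epoch activation probability (study presets: 0.1, 0.25,
#'   0.5, 0.75).
#' @param duration_range twitch duration range in ms, drawn uniformly
#'   (presets: 50-100, 450-500, 950-1000).
#' @param gain_range smoothing-gain range for the pulse shape, drawn
#'   uniformly per twitch.
#' @param epoch decision-epoch length in seconds. The default (0.2 s, i.e.
#'   ~0.5 twitches/s per muscle at `p = 0.1`) is in the range of observed
#'   fetal per-muscle twitch rates; see the package vignette.
#' @return An object of class `apg_config`.
#' @export
apg_config <- function(variant = c("full", "no_cocontraction",
                                   "symmetrical_only", "in_phase_only",
                                   "phasic"),
                       p = 0.1, duration_range = c(50, 100),
                       gain_range = c(0.5, 0.8), epoch = 0.2) {
  variant <- match.arg(variant)
  stopifnot(p >= 0, p <= 1, length(duration_range) == 2,
            duration_range[1] > 0, diff(duration_range) >= 0,
            all(gain_range > 0), all(gain_range <= 1), epoch > 0)
  structure(list(variant = variant, p = p,
                 duration_range = duration_range,
                 gain_range = gain_range, epoch = epoch),
            class = "apg_config")
}

#' Draw one twitch event
#'
#' Samples amplitude ~ U(0, 1), duration ~ U(duration range) and smoothing
#' gain ~ U(gain range) from R's global RNG stream.
#'
#' @param config an [apg_config()].
#' @param muscle target motoneuron index (1-4, order LE, LF, RF, RE).
#' @param onset onset time in seconds.
#' @return list with fields `muscle`, `onset`, `amplitude`, `duration`
#'   (seconds) and `gain`.
#' @export
sample_twitch <- function(config, muscle = 1L, onset = 0) {
  list(muscle = muscle, onset = onset,
       amplitude = runif(1),
       duration = runif(1, config$duration_range[1],
                        config$duration_range[2]) / 1000,
       gain = runif(1, config$gain_range[1], config$gain_range[2]))
}

# per-step waveform samples for one event: square pulse of the event's
# amplitude/duration passed through the one-step smoother with the event's
# gain; truncated to zero once it decays below 1% of the amplitude
twitch_samples <- function(amplitude, duration, gain, dt) {
  n1 <- max(1L, as.integer(round(duration / dt)))
  rise <- amplitude * (1 - (1 - gain)^(seq_len(n1)))
  v_end <- rise[n1]
  tail <- numeric(0)
  if (gain < 1 && v_end > 0.01 * amplitude) {
    k <- ceiling(log(0.01 * amplitude / v_end) / log(1 - gain))
    if (k > 0) {
      tail <- v_end * (1 - gain)^(seq_len(k))
      tail <- tail[tail >= 0.01 * amplitude]
    }
  }
  c(rise, tail)
}

#' Twitch drive waveform
#'
#' Evaluates the smoothed drive of one twitch event at arbitrary times:
#' zero before onset, rising toward the amplitude during the pulse as
#' `amplitude * (1 - (1 - gain)^n)` after `n` steps, then decaying
#' geometrically and truncated to zero below 1% of the amplitude (after
#' which the motoneuron counts as idle again).
#'
#' @param event a twitch event as returned by [sample_twitch()].
#' @param t numeric vector of times (seconds).
#' @param dt sampling step of the smoother.
#' @return drive values in \[0, 1\] at `t`.
#' @export
twitch_waveform <- function(event, t, dt = 0.010) {
  w <- twitch_samples(event$amplitude, event$duration, event$gain, dt)
  n <- floor((t - event$onset) / dt) + 1
  out <- numeric(length(t))
  ok <- n >= 1 & n <= length(w)
  out[ok] <- w[n[ok]]
  out
}

#' Generate the per-motoneuron APG drive stream
#'
#' Event-driven construction of the full drive matrix for a run. Decisions
#' are taken once per epoch per idle motoneuron (or idle joint pair for the
#' symmetrical/in-phase variants); a motoneuron is busy until its waveform
#' has decayed below 1% of the twitch amplitude. Under `no_cocontraction` a
#' twitch is cancelled when the same-limb antagonist is still active at the
#' proposed onset, which guarantees that same-limb antagonist drives are
#' never simultaneously positive.
#'
#' @param config an [apg_config()] (variant must not be `"phasic"`).
#' @param n_steps number of time steps.
#' @param dt step length in seconds.
#' @return list with `drive` (an `n_steps` x 4 matrix, columns LE, LF, RF,
#'   RE) and `events` (data.frame of the realized twitches).
#' @export
generate_apg_drive <- function(config, n_steps, dt = 0.010) {
  stopifnot(inherits(config, "apg_config"))
  if (config$variant == "phasic") {
    stop("use apg_drive_from_script() for phasic schedules", call. = FALSE)
  }
  drive <- matrix(0, n_steps, 4, dimnames = list(NULL, MUSCLES))
  busy <- rep(1L, 4)  # first step index at which the motoneuron is idle
  ev <- list()
  epoch_steps <- max(1L, as.integer(round(config$epoch / dt)))
  onsets <- seq.int(1L, n_steps, by = epoch_steps)

  place <- function(m, onset, amplitude, duration, gain) {
    w <- twitch_samples(amplitude, duration, gain, dt)
    idx <- onset:min(n_steps, onset + length(w) - 1L)
    drive[idx, m] <<- w[seq_along(idx)]
    busy[m] <<- onset + length(w)
    ev[[length(ev) + 1L]] <<- data.frame(
      muscle = MUSCLES[m], onset = (onset - 1L) * dt,
      amplitude = amplitude, duration = duration, gain = gain)
  }

  pairs <- switch(config$variant,
    symmetrical_only = list(c(1L, 4L), c(2L, 3L)),
    in_phase_only = list(c(1L, 3L), c(2L, 4L)),
    NULL)

  for (onset in onsets) {
    if (is.null(pairs)) {
      for (m in 1:4) {
        if (busy[m] > onset) next
        if (runif(1) >= config$p) next
        if (config$variant == "no_cocontraction" &&
            busy[ANTAGONIST[m]] > onset) next
        e <- sample_twitch(config, m, (onset - 1L) * dt)
        place(m, onset, e$amplitude, e$duration, e$gain)
      }
    } else {
      for (pr in pairs) {
        if (any(busy[pr] > onset)) next
        if (runif(1) >= config$p) next
        e <- sample_twitch(config, pr[1], (onset - 1L) * dt)
        for (m in pr) place(m, onset, e$amplitude, e$duration, e$gain)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(muscle = character(), onset = numeric(),
               amplitude = numeric(), duration = numeric(), gain = numeric())
  drive[drive > 1] <- 1
  list(drive = drive, events = events)
}

#' Phasic activation schedule
#'
#' Deterministic schedules emulating centrally patterned drive. With four
#' muscles there are 16 binary activation permutations; `id` selects one
#' (bit order LE, LF, RF, RE; `id = 0` activates nothing). Alternatively an
#' explicit script can be supplied.
#'
#' @param id integer in 0..15 selecting a binary permutation.
#' @param muscles character or integer vector of muscles to activate
#'   (overrides `id`).
#' @param onset activation onset in seconds.
#' @param amplitude pulse amplitude in \[0, 1\].
#' @param duration pulse duration in seconds.
#' @param gain smoothing gain; 1 gives a raw square pulse.
#' @return data.frame with one row per activated muscle (columns `muscle`,
#'   `onset`, `amplitude`, `duration`, `gain`), usable with
#'   [apg_drive_from_script()].
#' @export
phasic_sequence <- function(id = NULL, muscles = NULL, onset = 0,
                            amplitude = 1, duration = 0.05, gain = 1) {
  if (is.null(muscles)) {
    if (is.null(id) || id < 0 || id > 15) {
      stop("phasic permutation id must be in 0..15", call. = FALSE)
    }
    muscles <- MUSCLES[bitwAnd(as.integer(id), c(1L, 2L, 4L, 8L)) > 0]
  } else if (is.numeric(muscles)) {
    muscles <- MUSCLES[muscles]
  }
  stopifnot(all(muscles %in% MUSCLES))
  if (length(muscles) == 0) {
    return(data.frame(muscle = character(), onset = numeric(),
                      amplitude = numeric(), duration = numeric(),
                      gain = numeric()))
  }
  data.frame(muscle = muscles, onset = onset, amplitude = amplitude,
             duration = duration, gain = gain, stringsAsFactors = FALSE)
}

#' Build a drive matrix from a scripted schedule
#'
#' Each script row is a timed pulse; overlapping pulses on one motoneuron
#' sum and the result is clipped to \[0, 1\].
#'
#' @param script data.frame with columns `muscle`, `onset`, `amplitude`,
#'   `duration`, `gain` (see [phasic_sequence()]).
#' @param n_steps,dt stream length and step.
#' @return an `n_steps` x 4 drive matrix.
#' @export
apg_drive_from_script <- function(script, n_steps, dt = 0.010) {
  drive <- matrix(0, n_steps, 4, dimnames = list(NULL, MUSCLES))
  for (r in seq_len(nrow(script))) {
    m <- match(script$muscle[r], MUSCLES)
    if (is.na(m)) stop("unknown muscle in script: ", script$muscle[r])
    w <- twitch_samples(script$amplitude[r], script$duration[r],
                        script$gain[r], dt)
    onset <- as.integer(round(script$onset[r] / dt)) + 1L
    idx <- onset:min(n_steps, onset + length(w) - 1L)
    idx <- idx[idx >= 1L]
    if (length(idx)) drive[idx, m] <- drive[idx, m] + w[seq_along(idx)]
  }
  drive[drive > 1] <- 1
  drive
}
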