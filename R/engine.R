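#' Simulation configuration
#'
#' Bundles every constant of the closed loop: plant, sensor wiring, filter
#' gains, plasticity constants and the activity pattern generator. Defaults
#' are the fetal training conditions: 10% muscle strength, twitch
#' probability 0.1, 50-100 ms twitches, 20,000 s at 10 ms steps with the
#' full Ia sensor.
#'
#' @param duration simulated time in seconds.
#' @param dt integration step in seconds.
#' @param snapshot_interval weight-matrix snapshot cadence in seconds (must
#'   be a multiple of `dt`).
#' @param muscle_strength extrafusal strength fraction MS in (0, 1\].
#' @param sensor afferent feeding the four learnable synapses of every
#'   motoneuron: `"Ia"`, `"Ia_alpha"`, `"Ib"` or `"II"`.
#' @param apg an [apg_config()].
#' @param plant a [plant_params()]; its `muscle_strength` and `dt` are
#'   overridden by the arguments above.
#' @param gains a [filter_gains()] list (defined per 10 ms step; rescaled
#'   automatically if `dt` differs).
#' @param leak_gain gain of the leak's rolling estimate (default: the slow
#'   mean-activity gain `K_M`).
#' @param hp_cutoff cutoff (Hz) of the plasticity high-pass filter.
#' @param eta_exponent,eta_scale,eta_max learning-rate law
#'   `eta = min(eta_max, eta_scale * Pbar^eta_exponent)`.
#' @param init_mean,init_sd,init_floor initial-weight distribution (see
#'   [init_weights()]).
#' @param learn logical; `FALSE` freezes all weights (probe/playback runs).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 20000, dt = 0.010, snapshot_interval = 500,
                       muscle_strength = 0.1, sensor = "Ia",
                       apg = apg_config(), plant = NULL,
                       gains = NULL, leak_gain = NULL, hp_cutoff = 0.05,
                       eta_exponent = 1, eta_scale = 0.04, eta_max = 0.001,
                       init_mean = 0.2, init_sd = 0.16, init_floor = 0.001,
                       apg_shunt = FALSE, learn = TRUE) {
  stopifnot(duration >= snapshot_interval || snapshot_interval == 0,
            abs(snapshot_interval / dt - round(snapshot_interval / dt)) < 1e-9)
  if (is.null(plant)) plant <- default_plant()
  plant$muscle_strength <- muscle_strength
  plant$dt <- dt
  if (is.null(gains)) gains <- filter_gains(dt = dt)
  if (is.null(leak_gain)) leak_gain <- gains$K_M
  sensor_code(sensor)  # validate
  structure(list(
    duration = duration, dt = dt, snapshot_interval = snapshot_interval,
    muscle_strength = muscle_strength, sensor = sensor, apg = apg,
    plant = plant, gains = gains, leak_gain = leak_gain,
    hp_cutoff = hp_cutoff, eta_exponent = eta_exponent,
    eta_scale = eta_scale, eta_max = eta_max, init_mean = init_mean,
    init_sd = init_sd, init_floor = init_floor, apg_shunt = apg_shunt,
    learn = learn
  ), class = "sim_config")
}

# parameter list handed to the compiled core
core_par <- function(config) {
  p <- config$plant
  list(dt = config$dt, damping = p$damping, gain = p$gain,
       muscle_strength = p$muscle_strength, v_ref = velocity_reference(p),
       limb_limit = p$limb_limit, wall_left = p$wall_left,
       wall_right = p$wall_right, limb_offset = p$limb_offset,
       stiction_fraction = p$stiction_fraction,
       K_A = config$gains$K_A, K_L = config$gains$K_L,
       K_M = config$gains$K_M, leak_gain = config$leak_gain,
       hp_gain = highpass_gain(config$hp_cutoff, config$dt),
       eta_exponent = config$eta_exponent, eta_scale = config$eta_scale,
       eta_max = config$eta_max, apg_shunt = config$apg_shunt)
}

#' Run one closed-loop simulation
#'
#' Per step: (1) the plant state is updated from the muscle forces and
#' contacts; (2) muscle force follows from current length and the previous
#' motoneuron output; (3) the sensor outputs and APG drive are integrated by
#' each motoneuron and the learnable weights adjusted. Fully deterministic
#' given the seed (the seed fixes both the initial weights and the twitch
#' stream).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param drive optional precomputed `n_steps x 4` drive matrix (e.g. from
#'   [apg_drive_from_script()]); replaces the stochastic APG.
#' @param weights optional 4x4 initial weight matrix (rows = motoneurons,
#'   columns = afferent muscle of origin; order LE, LF, RF, RE); default:
#'   random initial weights.
#' @param record logical; record per-step traces (memory-heavy, for short
#'   runs).
#' @param state optional state list from a previous run or snapshot to
#'   resume from.
#' @param start_step first step index (0-based) of this run segment, used
#'   when resuming.
#' @return An object of class `spinloop_sim`: list with `weights` (final
#'   4x4 matrix), `snapshots` (data.frame, one row per snapshot), `state`,
#'   `traces` (if recorded), `events`, `config`, `seed`.
#' @export
run_simulation <- function(config, seed = 1L, drive = NULL, weights = NULL,
                           record = FALSE, state = NULL, start_step = 0L) {
  n_total <- as.integer(round(config$duration / config$dt))
  set.seed(seed)
  W0 <- matrix(init_weights(16, config$init_mean, config$init_sd,
                            config$init_floor), 4, 4,
               dimnames = list(MUSCLES, MUSCLES))
  if (!is.null(weights)) {
    W0 <- matrix(as.numeric(weights), 4, 4, dimnames = list(MUSCLES, MUSCLES))
  }
  events <- NULL
  if (is.null(drive)) {
    gen <- generate_apg_drive(config$apg, n_total, config$dt)
    drive <- gen$drive
    events <- gen$events
  }
  if (start_step > 0L) {
    stopifnot(!is.null(state), start_step < n_total)
    drive <- drive[(start_step + 1L):n_total, , drop = FALSE]
  }
  snap_steps <- as.integer(round(config$snapshot_interval / config$dt))
  res <- .sim_core(drive, W0, sensor_code(config$sensor), core_par(config),
                   state, config$learn, snap_steps, record)
  finish_sim(res, config, seed, events, snap_steps, start_step)
}

finish_sim <- function(res, config, seed, events, snap_steps, start_step) {
  W <- res$W
  dimnames(W) <- list(MUSCLES, MUSCLES)
  snaps <- NULL
  if (snap_steps > 0 && nrow(res$snapshots) > 0) {
    snaps <- as.data.frame(res$snapshots)
    names(snaps) <- c("time_s", paste0("w_", rep(MUSCLES, each = 4), "_",
                                       rep(MUSCLES, 4)))
    snaps$time_s <- snaps$time_s + start_step * config$dt
  }
  traces <- NULL
  if (nrow(res$traces) > 0) {
    traces <- as.data.frame(res$traces)
    names(traces) <- c(paste0("P_", MUSCLES), paste0("A_", MUSCLES),
                       paste0("sens_", MUSCLES), "ext_l", "ext_r", "body",
                       "vel_l", "vel_r", "F_LW", "F_RW")
    traces <- cbind(time_s = (start_step + seq_len(nrow(traces))) * config$dt,
                    traces)
  }
  structure(list(weights = W, snapshots = snaps, state = res$state,
                 traces = traces, events = events, config = config,
                 seed = seed, n_steps = res$n_steps + start_step),
            class = "spinloop_sim")
}

#' @export
print.spinloop_sim <- function(x, ...) {
  cat("<spinloop_sim> ", x$n_steps, " steps (",
      x$n_steps * x$config$dt, " s), sensor ", x$config$sensor,
      ", MS ", x$config$muscle_strength, ", seed ", x$seed, "\n",
      "final weights:\n", sep = "")
  print(round(x$weights, 3))
  invisible(x)
}

#' Pure-R reference engine
#'
#' Implements the identical closed loop in plain R, operation for
#' operation, as an independent check on the compiled core. Intended for
#' short runs only.
#'
#' @inheritParams run_simulation
#' @return same structure as [run_simulation()] (without traces).
#' @export
run_simulation_r <- function(config, seed = 1L, drive = NULL,
                             weights = NULL) {
  n_total <- as.integer(round(config$duration / config$dt))
  set.seed(seed)
  W <- matrix(init_weights(16, config$init_mean, config$init_sd,
                           config$init_floor), 4, 4)
  if (!is.null(weights)) W <- matrix(as.numeric(weights), 4, 4)
  events <- NULL
  if (is.null(drive)) {
    gen <- generate_apg_drive(config$apg, n_total, config$dt)
    drive <- gen$drive
    events <- gen$events
  }
  par <- core_par(config)
  p <- config$plant
  dt <- config$dt
  gms <- p$gain * p$muscle_strength
  lim <- p$limb_limit
  off <- p$limb_offset
  stick <- p$stiction_fraction * gms * 2 * lim
  KA <- par$K_A; KL <- par$K_L; KM <- par$K_M
  Kleak <- par$leak_gain; Khp <- par$hp_gain
  vref <- par$v_ref

  ext_l <- 0; ext_r <- 0; body <- 0
  A <- rep(0, 4); num <- rep(0, 4); den <- rep(0, 4)
  leak_tr <- rep(0, 4); Pbar <- rep(0, 4); lp <- rep(0, 4); P <- rep(0, 4)
  lsig <- matrix(0, 4, 4)
  snap_steps <- as.integer(round(config$snapshot_interval / config$dt))
  snaps <- NULL

  for (t in seq_len(n_total)) {
    s <- pmax(0, c(lim - ext_l, lim + ext_l, lim + ext_r, lim - ext_r))
    f_l <- gms * (A[1] * s[1] - A[2] * s[2])
    f_r <- gms * (A[4] * s[4] - A[3] * s[3])
    new_l <- ext_l + (f_l / p$damping) * dt
    new_r <- ext_r + (f_r / p$damping) * dt
    new_l <- min(min(lim, body - off - p$wall_left), max(-lim, new_l))
    new_r <- min(min(lim, p$wall_right - off - body), max(-lim, new_r))
    gap <- new_l + new_r + 2 * off
    if (gap < 0) { new_l <- new_l - gap / 2; new_r <- new_r - gap / 2 }
    v_l <- (new_l - ext_l) / dt; v_r <- (new_r - ext_r) / dt
    p_l <- body - off - new_l; p_r <- body + off + new_r
    FLW <- if (p_l <= p$wall_left + 1e-9)
      max(0, gms * (lim + new_l) * (A[1] - A[2])) else 0
    FRW <- if (p_r >= p$wall_right - 1e-9)
      min(0, -gms * (lim + new_r) * (A[4] - A[3])) else 0
    if (FLW > 0 && FRW < 0) {
      FB <- FLW - FRW
      if (abs(FB) > stick) body <- body + (FB / p$damping) * dt
    }
    ext_l <- new_l; ext_r <- new_r

    Lno <- c(0.2 + 0.1 * (lim - ext_l), 0.2 + 0.1 * (lim + ext_l),
             0.2 + 0.1 * (lim + ext_r), 0.2 + 0.1 * (lim - ext_r))
    V <- pmin(1, pmax(-1, 0.1 * c(-v_l, v_l, v_r, -v_r) / vref))
    sens <- vapply(1:4, function(m) switch(config$sensor,
      Ia = spindle_Ia(Lno[m], V[m], A[m]),
      Ia_alpha = spindle_Ia_alpha(Lno[m], V[m]),
      Ib = gto_Ib(Lno[m], A[m]),
      II = spindle_II(Lno[m], A[m])), numeric(1))

    Anew <- numeric(4)
    for (i in 1:4) {
      syn <- sum(sens * pmax(0, W[i, ]))
      ss <- syn + drive[t, i]
      sd <- if (config$apg_shunt) ss else syn
      num[i] <- num[i] * (1 - KA) + ss * KA
      den[i] <- den[i] * (1 - KA) + sd * KA
      leak_tr[i] <- leak_tr[i] * (1 - Kleak) + sd * Kleak
      k <- max(0.5, 2 * leak_tr[i])
      P[i] <- min(1, max(-1, num[i] / (k + den[i])))
      Pp <- max(0, P[i])
      Pbar[i] <- Pbar[i] * (1 - KM) + Pp * KM
      lp[i] <- lp[i] * (1 - Khp) + P[i] * Khp
      hp <- P[i] - lp[i]
      if (config$learn) {
        eta <- min(config$eta_max,
                   max(0, config$eta_scale * Pbar[i]^config$eta_exponent))
        for (j in 1:4) {
          drv <- sens[j] * W[i, j] * (hp - Pbar[i])
          lsig[i, j] <- min(1, max(-1, lsig[i, j] * (1 - KL) + drv * KL))
          cc <- if (lsig[i, j] >= 0) 1 - W[i, j] else W[i, j]
          W[i, j] <- min(1, max(-1, W[i, j] + lsig[i, j] * eta * cc))
        }
      }
      Anew[i] <- max(0, (Pp - 0.1) / 0.9)
    }
    A <- Anew
    if (snap_steps > 0 && t %% snap_steps == 0) {
      snaps <- rbind(snaps, c(t * dt, as.numeric(t(W))))
    }
  }
  state <- list(ext_l = ext_l, ext_r = ext_r, body = body, A = A, num = num,
                den = den, leak_trace = leak_tr, Pbar = Pbar, lp = lp, P = P,
                W = as.numeric(t(W)), l = as.numeric(t(lsig)))
  res <- list(W = W, snapshots = if (is.null(snaps))
    matrix(0, 0, 17) else snaps, state = state,
    traces = matrix(0, 0, 0), n_steps = n_total)
  finish_sim(res, config, seed, events, snap_steps, 0L)
}

#' Summarize a weight matrix by functional relationship
#'
#' The 16 Ia-to-motoneuron synapses partition into four groups of four:
#' homonymous (diagonal), same-limb antagonist, contralateral in-phase
#' synergist (LE-RF, LF-RE) and contralateral mirror (LE-RE, LF-RF).
#'
#' @param W a 4x4 weight matrix (rows = motoneurons, columns = afferent
#'   muscle; order LE, LF, RF, RE), or a `spinloop_sim` object.
#' @return data.frame with columns `relationship`, `mean`, `sd`.
#' @export
summarize_weights <- function(W) {
  if (inherits(W, "spinloop_sim")) W <- W$weights
  stopifnot(is.matrix(W), all(dim(W) == c(4, 4)))
  rel <- relationship_matrix()
  groups <- c("homonymous", "antagonist", "in_phase", "mirror")
  data.frame(
    relationship = groups,
    mean = vapply(groups, function(g) mean(W[rel == g]), numeric(1)),
    sd = vapply(groups, function(g) sd(W[rel == g]), numeric(1)),
    row.names = NULL
  )
}

#' @rdname summarize_weights
#' @export
relationship_matrix <- function() {
  rel <- matrix("", 4, 4, dimnames = list(MUSCLES, MUSCLES))
  for (i in 1:4) {
    rel[i, i] <- "homonymous"
    rel[i, ANTAGONIST[i]] <- "antagonist"
    rel[i, IN_PHASE[i]] <- "in_phase"
    rel[i, MIRROR[i]] <- "mirror"
  }
  rel
}

# pooled per-relationship means over replicate runs
pool_relationship <- function(sims) {
  rel <- relationship_matrix()
  groups <- c("homonymous", "antagonist", "in_phase", "mirror")
  per_run <- vapply(sims, function(s)
    vapply(groups, function(g) mean(s$weights[rel == g]), numeric(1)),
    numeric(4))
  data.frame(relationship = groups,
             mean = rowMeans(per_run),
             sd = apply(per_run, 1, sd),
             row.names = NULL)
}

#' Train replicate networks
#'
#' Runs `n` simulations that differ only in their seed (`seed + 0 ... n-1`),
#' i.e. in the initial weight randomization and the twitch stream.
#'
#' @param config a [sim_config()].
#' @param n number of replicates.
#' @param seed base seed; replicate i uses `seed + i - 1`.
#' @return list of `spinloop_sim` objects with a `summary` attribute
#'   (pooled per-relationship means/SDs).
#' @export
run_replicates <- function(config, n = 3, seed = 1L) {
  sims <- lapply(seq_len(n), function(i) run_simulation(config, seed + i - 1L))
  attr(sims, "summary") <- pool_relationship(sims)
  sims
}

#' Muscle-strength sweep
#'
#' Re-trains the network across a grid of muscle strengths (and optionally
#' twitch probabilities and duration ranges) and reports the pooled
#' per-relationship end weights for each condition.
#'
#' @param strengths muscle-strength grid.
#' @param p twitch probabilities to cross.
#' @param duration_ranges list of twitch duration ranges (ms).
#' @param n replicates per condition.
#' @param duration run length in seconds (reduced runs suffice to resolve
#'   the crossing; see the package vignette).
#' @param seed base seed.
#' @param ... further arguments to [sim_config()].
#' @return data.frame with one row per condition x relationship.
#' @export
run_strength_sweep <- function(strengths = seq(0.1, 1, by = 0.1), p = 0.1,
                               duration_ranges = list(c(50, 100)), n = 2,
                               duration = 10000, seed = 1L, ...) {
  grid <- expand.grid(ms = strengths, p = p,
                      dur = seq_along(duration_ranges))
  out <- lapply(seq_len(nrow(grid)), function(r) {
    dr <- duration_ranges[[grid$dur[r]]]
    cfg <- sim_config(duration = duration,
                      muscle_strength = grid$ms[r],
                      apg = apg_config(p = grid$p[r], duration_range = dr),
                      ...)
    sims <- run_replicates(cfg, n = n, seed = seed + 1000L * (r - 1L))
    s <- attr(sims, "summary")
    cbind(muscle_strength = grid$ms[r], p = grid$p[r],
          duration_min = dr[1], duration_max = dr[2], s)
  })
  do.call(rbind, out)
}

#' Homonymous/antagonist crossing and reversal strengths
#'
#' From a strength sweep, locates where the mean antagonist end weight
#' equals and where it first strictly exceeds the mean homonymous end
#' weight. The crossing is reported on the sweep's grid: around a sign
#' change of the homonymous-antagonist difference it is the grid point
#' whose difference is closest to zero; if the two group means approach
#' each other without a strict sign change on the grid, the grid point of
#' closest approach is reported. The reversal requires a strict excess and
#' is `NA` when none occurs.
#'
#' @param sweep output of [run_strength_sweep()] (single p / duration
#'   condition).
#' @return list with `crossing` and `reversal` muscle strengths (fractions;
#'   `reversal` is `NA` if not reached on the grid).
#' @export
weight_crossing <- function(sweep) {
  hom <- sweep[sweep$relationship == "homonymous", ]
  ant <- sweep[sweep$relationship == "antagonist", ]
  o <- order(hom$muscle_strength)
  ms <- hom$muscle_strength[o]
  diff <- hom$mean[o] - ant$mean[o]
  reversal <- if (any(diff < 0)) ms[which(diff < 0)[1]] else NA_real_
  flip <- which(diff[-1] < 0 & diff[-length(diff)] >= 0)
  crossing <- if (length(flip)) {
    i <- flip[1]
    if (abs(diff[i]) <= abs(diff[i + 1])) ms[i] else ms[i + 1]
  } else {
    ms[which.min(abs(diff))]
  }
  list(crossing = crossing, reversal = reversal)
}

#' Sensor-ablation control experiments
#'
#' Replaces the afferent feeding all four learnable synapses of every
#' motoneuron and retrains: `"Ia_alpha"` (no fusimotor effect) at low or
#' full muscle strength, `"Ib"` (force feedback) or `"II"` (length
#' feedback).
#'
#' @param sensor sensor wiring (see [sim_config()]).
#' @param muscle_strength MS fraction.
#' @param n replicates.
#' @param duration run length in seconds.
#' @param seed base seed.
#' @param ... further arguments to [sim_config()].
#' @return list of sims with pooled `summary` attribute (as
#'   [run_replicates()]).
#' @export
run_control <- function(sensor, muscle_strength = 0.1, n = 3,
                        duration = 20000, seed = 1L, ...) {
  cfg <- sim_config(duration = duration, muscle_strength = muscle_strength,
                    sensor = sensor, ...)
  run_replicates(cfg, n = n, seed = seed)
}

#' Reflex probe: response to a single twitch pulse
#'
#' Injects a square pulse (default 50 ms, 100% amplitude) into one
#' motoneuron's drive synapse of a network with fixed weights (learning
#' disabled) and records motoneuron and kinematic responses. The
#' antagonist-response flag reports whether the same-limb antagonist muscle
#' was activated at any point from the pulse onset on (the stretch reflex
#' elicited by the evoked limb movement).
#'
#' @param weights 4x4 weight matrix to probe (e.g. trained diagonal).
#' @param muscle_strength MS fraction.
#' @param muscle pulsed motoneuron (name or index).
#' @param amplitude,pulse_duration pulse parameters (fraction, seconds).
#' @param onset pulse onset in seconds.
#' @param duration total probe duration in seconds.
#' @param ... further arguments to [sim_config()].
#' @return list with `traces` (per-step data.frame), `antagonist_response`
#'   (logical), `response_duration` (seconds the pulsed muscle stayed
#'   active) and `peak_displacement` (world units).
#' @export
probe_reflex <- function(weights, muscle_strength = 0.1, muscle = "LE",
                         amplitude = 1, pulse_duration = 0.05, onset = 1,
                         duration = 15, ...) {
  if (is.character(muscle)) muscle <- match(muscle, MUSCLES)
  stopifnot(muscle %in% 1:4)
  cfg <- sim_config(duration = duration, snapshot_interval = 0,
                    muscle_strength = muscle_strength, learn = FALSE, ...)
  n_steps <- as.integer(round(duration / cfg$dt))
  script <- phasic_sequence(muscles = muscle, onset = onset,
                            amplitude = amplitude,
                            duration = pulse_duration, gain = 1)
  drive <- apg_drive_from_script(script, n_steps, cfg$dt)
  sim <- run_simulation(cfg, seed = 1L, drive = drive, weights = weights,
                        record = TRUE)
  tr <- sim$traces
  after <- tr$time_s >= onset
  a_hom <- tr[[paste0("A_", MUSCLES[muscle])]]
  a_ant <- tr[[paste0("A_", MUSCLES[ANTAGONIST[muscle]])]]
  ext <- if (muscle <= 2) tr$ext_l else tr$ext_r
  list(traces = tr,
       antagonist_response = any(a_ant[after] > 0),
       response_duration = sum(a_hom[after] > 0) * cfg$dt,
       peak_displacement = max(abs(ext[after])))
}

#' Playback of a phasic schedule with and without the network
#'
#' Runs a scripted activation schedule either open loop (the drive is the
#' muscle activation, no network) or through the motoneurons with fixed
#' weights. Because the motoneuron integrates its drive leakily, response
#' amplitudes with the network connected are reduced relative to open-loop
#' playback.
#'
#' @param script schedule data.frame (see [phasic_sequence()]).
#' @param weights 4x4 weight matrix used when `network = TRUE`.
#' @param network route the drive through the motoneurons?
#' @param muscle_strength MS fraction.
#' @param duration playback length in seconds.
#' @param ... further arguments to [sim_config()].
#' @return list with `traces` (per-step data.frame including `A_*`
#'   activation columns) and `network` flag.
#' @export
run_playback <- function(script, weights = diag(4), network = TRUE,
                         muscle_strength = 0.1, duration = 19, ...) {
  cfg <- sim_config(duration = duration, snapshot_interval = 0,
                    muscle_strength = muscle_strength, learn = FALSE, ...)
  n_steps <- as.integer(round(duration / cfg$dt))
  drive <- apg_drive_from_script(script, n_steps, cfg$dt)
  if (network) {
    sim <- run_simulation(cfg, seed = 1L, drive = drive, weights = weights,
                          record = TRUE)
    return(list(traces = sim$traces, network = TRUE))
  }
  # open loop: the schedule's drive is applied to the muscles directly
  colnames(drive) <- paste0("A_", MUSCLES)
  df <- run_simulation_open(cfg, drive)
  list(traces = df, network = FALSE)
}

# run the plant open loop under a prescribed activation stream (no network)
run_simulation_open <- function(config, activations) {
  p <- config$plant
  dt <- config$dt
  n <- nrow(activations)
  st <- plant_state()
  out <- matrix(0, n, 7)
  for (t in seq_len(n)) {
    st <- step_plant(st, pmin(1, pmax(0, activations[t, ])), p, dt)
    out[t, ] <- c(t * dt, st$ext_l, st$ext_r, st$body,
                  st$vel_l, st$vel_r, st$vel_body)
  }
  df <- as.data.frame(out)
  names(df) <- c("time_s", "ext_l", "ext_r", "body", "vel_l", "vel_r",
                 "vel_body")
  cbind(df, as.data.frame(activations))
}

#' Export a recorded state trace as CSV
#'
#' Writes the per-step trace of a recorded run: time, limb and body
#' positions, normalized muscle lengths and velocities and muscle
#' activations (muscle order LE, LF, RF, RE).
#'
#' @param sim a `spinloop_sim` run with `record = TRUE`.
#' @param path output file.
#' @return the exported data.frame, invisibly.
#' @export
export_trace <- function(sim, path) {
  tr <- sim$traces
  if (is.null(tr)) stop("run was not recorded; rerun with record = TRUE")
  p <- sim$config$plant
  lim <- p$limb_limit
  vref <- velocity_reference(p)
  L <- cbind(0.2 + 0.1 * (lim - tr$ext_l), 0.2 + 0.1 * (lim + tr$ext_l),
             0.2 + 0.1 * (lim + tr$ext_r), 0.2 + 0.1 * (lim - tr$ext_r))
  V <- 0.1 * cbind(-tr$vel_l, tr$vel_l, tr$vel_r, -tr$vel_r) / vref
  V[V > 1] <- 1
  V[V < -1] <- -1
  colnames(L) <- paste0("L_", MUSCLES)
  colnames(V) <- paste0("V_", MUSCLES)
  out <- cbind(data.frame(time_s = tr$time_s, x_L = -tr$ext_l,
                          x_R = tr$ext_r, body = tr$body), L, V,
               tr[paste0("A_", MUSCLES)])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
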