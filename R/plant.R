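#' Musculoskeletal plant parameters
#'
#' The plant is a one-dimensional, viscosity-dominated body with two limbs,
#' each pulled by an antagonist pair of spring-like muscles that can pull but
#' not push (force = gain * activation * spring length, rest length zero).
#' Limb velocity is proportional to net force (overdamped, first-order
#' dynamics); the body additionally has stiction so that it only moves when
#' braced between both walls with sufficient net force.
#'
#' Geometry: each limb travels `limb_limit` = 4 world units to either side of
#' its neutral position, so each muscle's spring length spans \[0, 8\] world
#' units, mapping linearly (slope 0.1 per unit, neutral 0.6) onto the
#' normalized muscle length \[0.2, 1.0\] used by the sensors.
#'
#' @param damping total viscous coefficient (limb velocity = force / damping).
#' @param muscle_strength global extrafusal force scale MS in (0, 1\];
#'   0.1 emulates the weak fetal stage, 1.0 full adult strength.
#' @param gain muscle force gain G (force per unit spring length at full
#'   activation and MS = 1). `NULL` calibrates G so that one maximally
#'   activated muscle traverses the full limb range in ~2 s
#'   (see [calibrate_muscle_gain()]).
#' @param stiction_fraction body stiction threshold as a fraction of the
#'   maximal muscle force `G * MS * 2 * limb_limit`.
#' @param limb_limit anatomical stop, world units from neutral.
#' @param wall_left,wall_right world coordinates of the walls.
#' @param limb_offset distance from body centre to each limb's neutral
#'   position.
#' @param dt integration time step in seconds.
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(damping = 2.0, muscle_strength = 1.0, gain = NULL,
                         stiction_fraction = 0.5, limb_limit = 4,
                         wall_left = -7, wall_right = 7, limb_offset = 3,
                         dt = 0.010) {
  stopifnot(damping > 0, muscle_strength > 0, muscle_strength <= 1,
            stiction_fraction >= 0, limb_limit == 4, dt > 0)
  p <- structure(list(
    damping = damping, muscle_strength = muscle_strength, gain = gain,
    stiction_fraction = stiction_fraction, limb_limit = limb_limit,
    wall_left = wall_left, wall_right = wall_right,
    limb_offset = limb_offset, dt = dt
  ), class = "plant_params")
  if (is.null(p$gain)) p$gain <- calibrate_muscle_gain(p, dt = dt)
  p
}

# peak normalized stretch speed (1/s): a fully activated antagonist at MS = 1
# acting on the longest spring; used to normalize V into [-1, 1]
velocity_reference <- function(params) {
  0.1 * params$gain * (2 * params$limb_limit) / params$damping
}

#' Plant state
#'
#' Limb displacements are measured from each limb's neutral position,
#' positive toward extension (outward); velocities are in the same frame.
#'
#' @param ext_l,ext_r limb displacements toward extension, world units in
#'   \[-4, 4\].
#' @param body body position, world units.
#' @param vel_l,vel_r,vel_body velocities (world units / s).
#' @param contact_l,contact_r reaction forces absorbed by stops/contacts at
#'   the last step (outward-positive frame).
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(ext_l = 0, ext_r = 0, body = 0,
                        vel_l = 0, vel_r = 0, vel_body = 0,
                        contact_l = 0, contact_r = 0) {
  structure(list(ext_l = ext_l, ext_r = ext_r, body = body,
                 vel_l = vel_l, vel_r = vel_r, vel_body = vel_body,
                 contact_l = contact_l, contact_r = contact_r),
            class = "plant_state")
}

# spring lengths (world units, in [0, 8]) in muscle order LE, LF, RF, RE
spring_lengths <- function(state, params) {
  lim <- params$limb_limit
  # order LE, LF, RF, RE
  c(lim - state$ext_l, lim + state$ext_l,
    lim + state$ext_r, lim - state$ext_r)
}

#' Limb displacement to normalized muscle kinematics
#'
#' Maps a limb displacement (positive toward extension) and velocity onto
#' one muscle's normalized length and velocity. The map is linear with slope
#' 0.1 normalized units per world unit; the neutral position maps to
#' L = 0.6, and a displacement of +4 fully shortens the extensor (L = 0.2)
#' while stretching the flexor to L = 1.0. Velocity is scaled so the fastest
#' achievable stretch (full-strength antagonist on the longest spring) maps
#' to +1, and clipped to \[-1, 1\].
#'
#' @param displacement limb displacement from neutral toward extension,
#'   world units in \[-4, 4\].
#' @param side `"extensor"` or `"flexor"`.
#' @param velocity limb velocity, world units / s (positive toward
#'   extension).
#' @param params a [plant_params()] object (supplies the velocity scale).
#' @return list with components `L` (in \[0.2, 1\]) and `V` (in \[-1, 1\]).
#' @export
limb_to_muscle_kinematics <- function(displacement,
                                      side = c("extensor", "flexor"),
                                      velocity = 0,
                                      params = default_plant()) {
  side <- match.arg(side)
  if (any(abs(displacement) > params$limb_limit + 1e-9)) {
    stop("limb displacement outside anatomical limits", call. = FALSE)
  }
  sgn <- if (side == "extensor") -1 else 1
  L <- 0.6 + sgn * 0.1 * displacement
  V <- pmin(1, pmax(-1, sgn * 0.1 * velocity / velocity_reference(params)))
  list(L = L, V = V)
}

#' Net force on one limb
#'
#' Evaluates the limb force balance in world coordinates: antagonist spring
#' terms (activation times spring length times `G * MS`, clamped so that
#' muscles never push), viscous drag, and the external contact force. For
#' the left limb, negative force points outward (leftward).
#'
#' @param activations numeric vector of 4 muscle activations in \[0, 1\],
#'   order LE, LF, RF, RE.
#' @param state a [plant_state()].
#' @param params a [plant_params()].
#' @param side `"left"` or `"right"`.
#' @return net force (world-frame sign convention).
#' @export
limb_net_force <- function(activations, state, params,
                           side = c("left", "right")) {
  side <- match.arg(side)
  check_range(activations, 0, 1, "activations")
  gms <- params$gain * params$muscle_strength
  s <- pmax(0, spring_lengths(state, params))
  if (side == "left") {
    # world x: outward is negative for the left limb
    -gms * activations[1] * s[1] + gms * activations[2] * s[2] -
      (-state$vel_l) * params$damping - (-state$contact_l)
  } else {
    gms * activations[4] * s[4] - gms * activations[3] * s[3] -
      state$vel_r * params$damping - state$contact_r
  }
}

#' Wall and body forces
#'
#' Forces transmitted to the body when a limb is braced against its wall.
#' The left-wall force is valid only when positive, the right-wall force
#' only when negative, and the body force is nonzero only when both limbs
#' brace simultaneously (`F_LW > 0` and `F_RW < 0`); otherwise the body
#' feels no propulsive force. Stiction is applied on top of this in
#' [step_plant()].
#'
#' @inheritParams limb_net_force
#' @return list with components `F_LW`, `F_RW`, `F_Body`.
#' @export
wall_and_body_forces <- function(activations, state, params) {
  check_range(activations, 0, 1, "activations")
  gms <- params$gain * params$muscle_strength
  s <- pmax(0, spring_lengths(state, params))
  p_l <- state$body - params$limb_offset - state$ext_l
  p_r <- state$body + params$limb_offset + state$ext_r
  eps <- 1e-9
  F_LW <- if (p_l <= params$wall_left + eps) {
    max(0, gms * s[2] * (activations[1] - activations[2]))
  } else 0
  F_RW <- if (p_r >= params$wall_right - eps) {
    min(0, -gms * s[3] * (activations[4] - activations[3]))
  } else 0
  F_Body <- if (F_LW > 0 && F_RW < 0) {
    F_LW - F_RW - state$vel_body * params$damping
  } else 0
  list(F_LW = unname(F_LW), F_RW = unname(F_RW), F_Body = unname(F_Body))
}

#' Advance the plant by one time step
#'
#' Explicit first-order (velocity proportional to force) update: each limb
#' moves with velocity `force / damping`, positions are clamped at the
#' anatomical stops, at the walls and at limb-limb contact, and the force
#' absorbed by a clamp is recorded as that limb's contact reaction. The body
#' moves only when braced between both walls with a net force exceeding the
#' stiction threshold.
#'
#' @inheritParams limb_net_force
#' @param dt time step in seconds.
#' @return the updated [plant_state()].
#' @export
step_plant <- function(state, activations, params, dt = params$dt) {
  check_range(activations, 0, 1, "activations")
  gms <- params$gain * params$muscle_strength
  lim <- params$limb_limit
  off <- params$limb_offset
  s <- pmax(0, spring_lengths(state, params))

  # outward-positive net non-viscous force per limb
  f_l <- gms * (activations[1] * s[1] - activations[2] * s[2])
  f_r <- gms * (activations[4] * s[4] - activations[3] * s[3])
  if (!is.finite(f_l) || !is.finite(f_r)) {
    stop("non-finite limb force; state: ",
         paste(deparse(unclass(state)), collapse = ""), call. = FALSE)
  }
  new_l <- state$ext_l + (f_l / params$damping) * dt
  new_r <- state$ext_r + (f_r / params$damping) * dt

  # anatomical stops and wall reach (walls can bind earlier if the body has
  # shifted toward one of them)
  ub_l <- min(lim, state$body - off - params$wall_left)
  ub_r <- min(lim, params$wall_right - off - state$body)
  new_l <- min(ub_l, max(-lim, new_l))
  new_r <- min(ub_r, max(-lim, new_r))
  # limb-limb contact: world positions may not cross
  gap <- new_l + new_r + 2 * off
  if (gap < 0) {
    new_l <- new_l - gap / 2
    new_r <- new_r - gap / 2
  }

  v_l <- (new_l - state$ext_l) / dt
  v_r <- (new_r - state$ext_r) / dt
  contact_l <- f_l - params$damping * v_l
  contact_r <- f_r - params$damping * v_r

  st2 <- plant_state(ext_l = new_l, ext_r = new_r, body = state$body,
                     vel_l = v_l, vel_r = v_r, vel_body = 0,
                     contact_l = contact_l, contact_r = contact_r)
  wb <- wall_and_body_forces(activations, st2, params)
  thresh <- params$stiction_fraction * gms * 2 * lim
  if (abs(wb$F_Body) > thresh) {
    st2$vel_body <- wb$F_Body / params$damping
    st2$body <- st2$body + st2$vel_body * dt
  }
  st2
}

#' Calibrate the muscle force gain
#'
#' Finds the gain G such that a single maximally activated muscle (A = 1,
#' antagonist silent, MS = 1) drives its limb from one anatomical stop to
#' the other in `target` seconds. Because the spring force vanishes as the
#' muscle shortens, the approach to the far stop is asymptotic; the
#' traverse is scored as complete when 99% of the travel is covered.
#' The gain is found by bisection on simulated traverses.
#'
#' @param params a [plant_params()] (its `gain` field is ignored).
#' @param dt integration step used for the calibration runs.
#' @param target desired traverse time in seconds.
#' @param tol tolerance on the traverse time.
#' @return the calibrated gain (numeric scalar).
#' @export
calibrate_muscle_gain <- function(params, dt = params$dt, target = 2.0,
                                  tol = 1e-3) {
  traverse_time <- function(G) {
    s <- 2 * params$limb_limit          # longest spring, at the far stop
    goal <- 0.01 * s                    # 99% of travel covered
    t <- 0
    while (s > goal) {
      s <- s - (G * s / params$damping) * dt
      t <- t + dt
      if (t > 120) return(Inf)
    }
    t
  }
  lo <- 0.05; hi <- 200
  if (traverse_time(lo) < target || traverse_time(hi) > target) {
    stop("muscle gain calibration failed: target traverse time not bracketed")
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (traverse_time(mid) > target) lo <- mid else hi <- mid
    if (hi - lo < 1e-8) break
  }
  G <- (lo + hi) / 2
  if (abs(traverse_time(G) - target) > max(tol, 2 * dt)) {
    stop("muscle gain calibration did not converge")
  }
  G
}

# memoized default plant (calibrated gain), used where a params object is
# optional
plant_cache <- new.env(parent = emptyenv())
default_plant <- function() {
  if (is.null(plant_cache$p)) plant_cache$p <- plant_params()
  plant_cache$p
}
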