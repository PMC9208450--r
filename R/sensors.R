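#' Spindle group II afferent transfer function
#'
#' Length-coding secondary spindle afferent. The activation term models the
#' static fusimotor effect of beta-motoneuron drive on the chain/bag2
#' intrafusal fibres: an active muscle biases the receptor upward at any
#' length. Output reaches 1 only for a maximally stretched, maximally
#' activated muscle.
#'
#' @param L normalized muscle length in \[0.2, 1\] (0.6 = neutral limb
#'   position).
#' @param A muscle activation in \[0, 1\].
#' @return II output, clipped to \[0, 1\]. Vectorized.
#' @export
#' @examples
#' spindle_II(1, 1)    # 1.0
#' spindle_II(0.6, 0.5) # 0.5
spindle_II <- function(L, A) {
  check_range(L, 0.2, 1, "L")
  check_range(A, 0, 1, "A")
  clip01(((L - 0.2) * 1.25 + A) / 2)
}

#' Spindle group Ia afferent with beta-motoneuron fusimotor action
#'
#' Primary spindle afferent. Velocity sensitivity depends nonlinearly on
#' activation through the gain `1.5 + log10(A + 0.1)`: 0.5 for a passive
#' muscle, rising rapidly at light recruitment and saturating
#' logarithmically (dynamic fusimotor effect of the bag1 fibre). The direct
#' `A` term and the scaled group-II term carry the static fusimotor bias.
#'
#' @param L normalized muscle length in \[0.2, 1\].
#' @param V normalized muscle velocity in \[-1, 1\] (+1 = fastest achievable
#'   stretch).
#' @param A muscle activation in \[0, 1\].
#' @return Ia output, clipped to \[0, 1\]. Vectorized.
#' @export
#' @examples
#' spindle_Ia(0.2, 1, 0)  # passive muscle at max stretch velocity: 0.25
spindle_Ia <- function(L, V, A) {
  check_range(V, -1, 1, "V")
  II <- spindle_II(L, A)
  clip01(((1.5 + log10(A + 0.1)) * V + A + II * 0.2) / 2)
}

#' Spindle Ia afferent without fusimotor effect (alpha-only control)
#'
#' Ablated Ia used for control experiments emulating an organism with only
#' alpha-motoneurons: the receptor codes length and velocity but receives no
#' intrafusal drive, so it can only be excited by overt limb motion.
#'
#' @inheritParams spindle_Ia
#' @return Ia output, clipped to \[0, 1\]. Vectorized.
#' @export
spindle_Ia_alpha <- function(L, V) {
  check_range(L, 0.2, 1, "L")
  check_range(V, -1, 1, "V")
  clip01((L + V) / 2)
}

#' Golgi tendon organ (Ib) afferent
#'
#' Linear sensor of the active force generated by the muscle it sits in.
#' With the plant's spring-like muscles, active force is proportional to
#' activation times current length, so `Ib = A * L` on the normalized scale.
#'
#' @inheritParams spindle_II
#' @return Ib output, clipped to \[0, 1\]. Vectorized.
#' @export
gto_Ib <- function(L, A) {
  check_range(L, 0.2, 1, "L")
  check_range(A, 0, 1, "A")
  clip01(A * L)
}

#' Dense sensor evaluation over an input grid
#'
#' Evaluates one sensor transfer function over the full cross product of the
#' supplied input vectors, for tuning-surface (heatmap) regeneration and
#' export.
#'
#' @param sensor one of `"Ia"`, `"II"`, `"Ib"`, `"Ia_alpha"`.
#' @param L,V,A numeric vectors of input values; `V` is ignored for `II` and
#'   `Ib`, `A` for `Ia_alpha`.
#' @return A data.frame with columns `L`, `V`, `A`, `output`.
#' @export
sensor_grid <- function(sensor = c("Ia", "II", "Ib", "Ia_alpha"),
                        L = seq(0.2, 1, by = 0.1),
                        V = seq(-1, 1, by = 0.25),
                        A = seq(0, 1, by = 0.1)) {
  sensor <- match.arg(sensor)
  if (sensor %in% c("II", "Ib")) V <- 0
  if (sensor == "Ia_alpha") A <- 0
  g <- expand.grid(L = L, V = V, A = A, KEEP.OUT.ATTRS = FALSE)
  g$output <- switch(sensor,
    Ia = spindle_Ia(g$L, g$V, g$A),
    II = spindle_II(g$L, g$A),
    Ib = gto_Ib(g$L, g$A),
    Ia_alpha = spindle_Ia_alpha(g$L, g$V)
  )
  g
}

# sensor codes shared with the compiled core
sensor_code <- function(sensor) {
  switch(sensor, Ia = 1L, Ia_alpha = 2L, Ib = 3L, II = 4L,
         stop("unknown sensor wiring: ", sensor))
}

check_range <- function(x, lo, hi, name, tol = 1e-9) {
  if (any(!is.finite(x)) || any(x < lo - tol) || any(x > hi + tol)) {
    stop(sprintf("%s out of range [%g, %g]", name, lo, hi), call. = FALSE)
  }
  invisible(x)
}
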