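#' Filter gains for the neuron model
#'
#' First-order exponential smoother gains, defined per 10 ms step. When the
#' integration step differs from 10 ms the gains are rescaled as
#' `K' = 1 - (1 - K)^(dt / 0.01)` so that the underlying time constants are
#' preserved.
#'
#' @param K_A fast gain for synaptic activity smoothing.
#' @param K_L slow gain for the learning signal.
#' @param K_M very slow gain for the mean-activity trace (time constant
#'   ~250 s at 10 ms steps).
#' @param dt integration step in seconds the gains will be used at.
#' @return list of gains rescaled to `dt`.
#' @export
filter_gains <- function(K_A = 0.3, K_L = 0.001, K_M = 4.0e-5, dt = 0.010) {
  g <- lapply(list(K_A = K_A, K_L = K_L, K_M = K_M),
              rescale_gain, dt = dt)
  stopifnot(all(unlist(g) > 0), all(unlist(g) <= 1))
  g
}

#' @rdname filter_gains
#' @param K a gain defined per 10 ms step.
#' @export
rescale_gain <- function(K, dt, dt_ref = 0.010) {
  if (K <= 0 || K > 1) stop("filter gain must be in (0, 1]", call. = FALSE)
  if (dt == dt_ref) K else 1 - (1 - K)^(dt / dt_ref)
}

#' One-dimensional exponential smoother ("Kalman" filter)
#'
#' `y_t = y_{t-1} (1 - K) + x_t K`. Used throughout the model: fast synaptic
#' traces, the learning signal, the mean-activity trace, and the smoothing of
#' twitch drive pulses.
#'
#' @param previous previous output `y_{t-1}`.
#' @param input current input `x_t`.
#' @param gain smoothing gain K in (0, 1\].
#' @return updated output. Vectorized over `previous`/`input`.
#' @export
kalman_update <- function(previous, input, gain) {
  if (any(gain <= 0) || any(gain > 1)) {
    stop("filter gain must be in (0, 1]", call. = FALSE)
  }
  previous * (1 - gain) + input * gain
}

#' Activity-dependent shunting leak
#'
#' The resting leak of each neuron tracks twice a slow rolling estimate of
#' its total (unsigned) synaptic activation, with a floor of 0.5. A neuron
#' receiving sustained strong input therefore shunts itself, protecting the
#' output from saturation as synapses potentiate.
#'
#' @param trace current rolling estimate of `sum(P_j+ w_ij+)`.
#' @return leak value `k >= 0.5`.
#' @export
update_leak <- function(trace) {
  pmax(0.5, 2 * trace)
}

#' Create the state of one rate neuron
#'
#' All smoothed traces, the output and the mean activity start at zero.
#'
#' @return list with components `num` (smoothed signed synaptic sum), `den`
#'   (smoothed unsigned sum), `leak_trace` (slow rolling unsigned sum), `P`
#'   (output potential), `Pp` (its positive part), `Pbar` (mean activity) and
#'   `lp` (low-pass state of the plasticity high-pass filter).
#' @export
neuron_state <- function() {
  list(num = 0, den = 0, leak_trace = 0, P = 0, Pp = 0, Pbar = 0, lp = 0)
}

#' Advance one neuron by one time step
#'
#' Linear-summation rate neuron with shunting leak. The signed and unsigned
#' synaptic sums (including any fixed drive synapse) are smoothed with the
#' fast gain; the output is their ratio
#' `P = num / (k + den)` where the leak `k` tracks twice a slow rolling
#' estimate of the unsigned sum (floor 0.5). The mean activity trace `Pbar`
#' follows the positive part of the output with the very slow gain.
#'
#' @param state a [neuron_state()].
#' @param inputs presynaptic outputs `P_j+` in \[0, 1\] (one per synapse).
#' @param weights synaptic weights (signed; only the positive part is
#'   functional).
#' @param signs fixed synapse signs (+1 excitatory, -1 inhibitory).
#' @param gains a [filter_gains()] list.
#' @param leak_gain gain for the leak's rolling estimate (default: the slow
#'   mean-activity gain, making the leak a homeostatic background term).
#' @param hp_gain low-pass gain of the plasticity high-pass filter
#'   (default: 0.05 Hz cutoff at 10 ms steps).
#' @return updated state.
#' @export
neuron_step <- function(state, inputs, weights, signs = rep(1, length(weights)),
                        gains = filter_gains(), leak_gain = gains$K_M,
                        hp_gain = highpass_gain()) {
  check_range(inputs, 0, 1, "inputs")
  wp <- pmax(0, weights)
  s_signed <- sum(inputs * wp * signs)
  s_unsigned <- sum(inputs * wp)
  state$num <- kalman_update(state$num, s_signed, gains$K_A)
  state$den <- kalman_update(state$den, s_unsigned, gains$K_A)
  state$leak_trace <- kalman_update(state$leak_trace, s_unsigned, leak_gain)
  k <- update_leak(state$leak_trace)
  denom <- k + state$den
  stopifnot(denom > 0)
  state$P <- state$num / denom
  state$Pp <- max(0, state$P)
  state$Pbar <- kalman_update(state$Pbar, state$Pp, gains$K_M)
  state$lp <- kalman_update(state$lp, state$P, hp_gain)
  state
}

#' Motoneuron output to muscle activation
#'
#' A small hyperpolarizing bias compensates for the absence of inhibitory
#' neurons: output below 0.1 produces no muscle activation, and the
#' remaining range is rescaled to \[0, 1\].
#'
#' @param Pp positive part of the motoneuron output, in \[0, 1\].
#' @return muscle activation A in \[0, 1\]. Vectorized.
#' @export
muscle_activation <- function(Pp) {
  check_range(Pp, 0, 1, "Pp")
  pmax(0, (Pp - 0.1) / 0.9)
}
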