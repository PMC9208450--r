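#' Initialize synaptic weights
#'
#' Initial weights are sampled from a normal distribution at the low end of
#' the functional range (mean 0.2, sd 0.16); samples below 0.001 are redrawn
#' so every initial weight is positive. Uses R's global RNG stream, so
#' results are reproducible under `set.seed()`.
#'
#' @param n number of weights.
#' @param mean,sd parameters of the sampling distribution.
#' @param floor redraw threshold.
#' @return numeric vector of `n` weights, all `>= floor`.
#' @export
init_weights <- function(n, mean = 0.2, sd = 0.16, floor = 0.001) {
  w <- rnorm(n, mean, sd)
  while (any(bad <- w < floor)) {
    w[bad] <- rnorm(sum(bad), mean, sd)
  }
  w
}

#' Low-pass gain of the plasticity high-pass filter
#'
#' The postsynaptic potential entering the learning signal is high-passed at
#' `cutoff` Hz (default 0.05 Hz), realized as
#' `hp(x) = x - lowpass(x)` with a first-order low-pass of gain
#' `1 - exp(-2 pi cutoff dt)`.
#'
#' @param cutoff cutoff frequency in Hz.
#' @param dt sampling step in seconds.
#' @return smoother gain in (0, 1).
#' @export
highpass_gain <- function(cutoff = 0.05, dt = 0.010) {
  1 - exp(-2 * pi * cutoff * dt)
}

#' High-pass filter a postsynaptic potential stream
#'
#' Removes the DC component of the neuron output so that the learning signal
#' responds to transients (the fast supralinear calcium signal) rather than
#' to tonic activity. Step response: jumps to the step size, then decays
#' with time constant `1 / (2 pi cutoff)` (~3.18 s at 0.05 Hz).
#'
#' @param x numeric vector, the potential sampled at `dt`.
#' @inheritParams highpass_gain
#' @param init initial low-pass state.
#' @return numeric vector, the high-passed stream.
#' @export
highpass_postsynaptic <- function(x, cutoff = 0.05, dt = 0.010, init = 0) {
  g <- highpass_gain(cutoff, dt)
  lp <- stats::filter(x * g, 1 - g, method = "recursive",
                      init = init * (1 - g))
  as.numeric(x - lp)
}

#' Learning-signal update
#'
#' The per-synapse learning signal is a slow smoothed covariance between the
#' presynaptic input (scaled by the current signed weight) and the deviation
#' of the high-passed postsynaptic potential from its running mean. Positive
#' covariance drives potentiation, negative covariance depression.
#'
#' @param l_prev previous learning signal.
#' @param pre presynaptic output `P_j+` in \[0, 1\].
#' @param w current signed synaptic weight.
#' @param post_hp high-passed postsynaptic potential.
#' @param post_mean mean-activity trace `Pbar` of the postsynaptic neuron.
#' @param K_L learning-signal smoother gain.
#' @return updated learning signal, clipped to \[-1, 1\]. Vectorized.
#' @export
learning_signal_step <- function(l_prev, pre, w, post_hp, post_mean,
                                 K_L = 0.001) {
  drive <- pre * w * (post_hp - post_mean)
  pmin(1, pmax(-1, kalman_update(l_prev, drive, K_L)))
}

#' Compensation factor
#'
#' Soft weight bound: potentiation steps scale with the remaining headroom
#' `1 - w`, depression steps with the weight itself, so weights approach but
#' never cross their limits and negative (nonfunctional) weights relax back
#' toward zero under a negative learning signal.
#'
#' @param w signed synaptic weight in \[-1, 1\].
#' @param l learning signal.
#' @return compensation factor. Vectorized.
#' @export
compensation_factor <- function(w, l) {
  ifelse(l >= 0, 1 - w, w)
}

#' Homeostatic learning rate
#'
#' The learning rate of a neuron scales with its mean activity trace,
#' `eta = scale * Pbar^exponent`, clamped to \[0, max\]: a silent neuron
#' learns nothing, and the cap bounds the per-step weight change of a
#' strongly active neuron at 0.001.
#'
#' @param Pbar mean activity in \[0, 1\].
#' @param exponent,scale shape of the activity dependence.
#' @param max upper clamp.
#' @return learning rate in \[0, max\]. Vectorized.
#' @export
learning_rate <- function(Pbar, exponent = 1, scale = 0.04, max = 0.001) {
  check_range(Pbar, 0, 1, "Pbar")
  pmin(max, pmax(0, scale * Pbar^exponent))
}

#' Apply one weight update
#'
#' `w' = w + l * eta * c`, clamped to \[-1, 1\]. Only the positive part of
#' the weight is functional downstream; the fixed drive synapse is never
#' passed through this update.
#'
#' @param w current signed weight.
#' @param l learning signal.
#' @param eta learning rate.
#' @param c compensation factor.
#' @return updated weight. Vectorized.
#' @export
weight_update <- function(w, l, eta, c) {
  pmin(1, pmax(-1, w + l * eta * c))
}
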