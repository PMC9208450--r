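test_that("initial weights are positive draws from the stated distribution", {
  set.seed(123)
  w <- init_weights(20000)
  expect_true(all(w >= 0.001))
  # oracle: closed-form mean of the truncated normal (redraw below 0.001)
  alpha <- (0.001 - 0.2) / 0.16
  mu_trunc <- 0.2 + 0.16 * dnorm(alpha) / (1 - pnorm(alpha))
  expect_equal(mean(w), mu_trunc, tolerance = 0.01)
  # determinism under a fixed seed
  set.seed(7); a <- init_weights(16)
  set.seed(7); b <- init_weights(16)
  expect_identical(a, b)
})

test_that("postsynaptic high-pass removes DC and has the stated step response", {
  n <- 3000
  out <- highpass_postsynaptic(rep(0.4, n))
  expect_lt(abs(out[n]), 1e-4)              # DC removed
  expect_equal(highpass_postsynaptic(rep(0, 100)), rep(0, 100))
  # unit step: jumps to ~1 and decays with tau = 1/(2 pi 0.05) ~ 3.18 s
  step <- highpass_postsynaptic(rep(1, n))
  expect_gt(step[1], 0.99)
  tau_steps <- round(1 / (2 * pi * 0.05) / 0.01)
  expect_equal(step[tau_steps] / step[1], exp(-1), tolerance = 0.02)
})

test_that("learning signal is the smoothed weighted covariance drive", {
  # direct evaluation of one update
  expect_equal(learning_signal_step(0, pre = 1, w = 0.5, post_hp = 0.2,
                                    post_mean = 0, K_L = 0.001), 1e-4)
  # zero presynaptic drive: geometric decay toward 0
  l <- 0.5
  l1 <- learning_signal_step(l, 0, 0.5, 0.3, 0.1, K_L = 0.001)
  expect_equal(l1, l * 0.999)
  # covariance null point: high-passed potential equals the running mean
  expect_equal(learning_signal_step(0.2, 1, 0.5, 0.15, 0.15, 0.001),
               0.2 * 0.999)
  # clipping to [-1, 1]
  expect_equal(learning_signal_step(1, 1, 1, 10, 0, K_L = 1), 1)
})

test_that("compensation factor soft-bounds the weights", {
  expect_equal(compensation_factor(0.2, 0.1), 0.8)
  expect_equal(compensation_factor(0.2, -0.1), 0.2)
  expect_equal(compensation_factor(1, 0.5), 0)   # no potentiation at the cap
})

test_that("learning rate scales with mean activity and clamps at 0.001", {
  expect_equal(learning_rate(0), 0)
  expect_equal(learning_rate(1), 0.001)
  expect_equal(learning_rate(0.01), 4e-4)
  expect_equal(learning_rate(0.3), 0.001)        # clamped
  # the quartic variant remains available through the exposed arguments
  expect_equal(learning_rate(0.3, exponent = 4, scale = 0.01), 8.1e-5)
})

test_that("weight updates follow the learning rule and its sign algebra", {
  expect_equal(weight_update(0.3, 0, 0.001, 0.7), 0.3)
  expect_equal(weight_update(0.5, 0.1, 0.001, 0.5), 0.50005)
  # negative weight with negative learning signal relaxes toward zero
  w <- -0.4
  w2 <- weight_update(w, -0.2, 0.001, compensation_factor(w, -0.2))
  expect_gt(w2, w)
  expect_lt(w2, 0)
  # clamping at the bounds under sustained extreme updates
  w <- 0.999
  for (i in 1:5000) w <- weight_update(w, 1, 0.001, compensation_factor(w, 1))
  expect_lte(w, 1)
  expect_gt(w, 0.999)
})

test_that("correlated pre/post activity potentiates, anticorrelated depresses", {
  run_pattern <- function(correlated) {
    n <- 4000
    post <- rep(0.05, n)
    bursts <- seq(200, n - 200, by = 400)
    for (b in bursts) post[b:(b + 20)] <- 0.5          # postsynaptic transients
    pre <- rep(0.02, n)
    off <- if (correlated) 0 else 200                  # bursts out of phase
    for (b in bursts) pre[((b + off):(b + off + 20))] <- 0.6
    hp <- highpass_postsynaptic(post)
    pbar <- numeric(n); y <- 0
    for (t in 1:n) { y <- kalman_update(y, max(0, post[t]), 4e-5); pbar[t] <- y }
    w <- 0.2; l <- 0
    for (t in 1:n) {
      l <- learning_signal_step(l, pre[t], w, hp[t], pbar[t])
      w <- weight_update(w, l, 0.001, compensation_factor(w, l))
    }
    w
  }
  expect_gt(run_pattern(TRUE), 0.2)
  expect_lt(run_pattern(FALSE), 0.2)
})
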