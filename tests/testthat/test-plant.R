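test_that("limb displacement maps linearly onto normalized muscle kinematics", {
  p <- unit_plant()
  k <- limb_to_muscle_kinematics(0, "extensor", 0, p)
  expect_equal(k$L, 0.6)
  expect_equal(k$V, 0)
  expect_equal(limb_to_muscle_kinematics(4, "extensor", 0, p)$L, 0.2)
  expect_equal(limb_to_muscle_kinematics(4, "flexor", 0, p)$L, 1.0)
  # extensor and flexor lengths always sum to 1.2
  for (d in seq(-4, 4, by = 0.5)) {
    expect_equal(limb_to_muscle_kinematics(d, "extensor", 0, p)$L +
                 limb_to_muscle_kinematics(d, "flexor", 0, p)$L, 1.2)
  }
  expect_error(limb_to_muscle_kinematics(4.5, "extensor", 0, p),
               "anatomical limits")
})

test_that("limb net force follows the antagonist spring balance", {
  p <- unit_plant()
  st <- plant_state()
  A0 <- rep(0, 4)
  expect_equal(limb_net_force(A0, st, p, "left"), 0)
  expect_equal(limb_net_force(A0, st, p, "right"), 0)
  # antagonist symmetry at neutral
  expect_equal(limb_net_force(c(0.4, 0.4, 0, 0), st, p, "left"), 0)
  # direct evaluation: extensor spring length 2 (world frame, force leftward)
  st2 <- plant_state(ext_l = 2)
  expect_equal(limb_net_force(c(0.5, 0, 0, 0), st2, p, "left"), -1.0)
  # muscle strength scales every spring term
  p01 <- unit_plant(ms = 0.1)
  expect_equal(limb_net_force(c(0.5, 0, 0, 0), st2, p01, "left"), -0.1)
})

test_that("wall and body forces respect their validity clamps", {
  p <- unit_plant()
  # no wall contact -> all zero
  wb <- wall_and_body_forces(c(1, 0, 0, 1), plant_state(), p)
  expect_equal(wb, list(F_LW = 0, F_RW = 0, F_Body = 0))
  # at the wall but flexor-dominated: raw force negative, clamped to zero
  at_walls <- plant_state(ext_l = 4, ext_r = 4)
  wb <- wall_and_body_forces(c(0, 1, 1, 0), at_walls, p)
  expect_equal(wb$F_LW, 0)
  expect_equal(wb$F_RW, 0)
  # symmetric extensor pushes f against both walls -> body force 2f
  a <- 0.5
  wb <- wall_and_body_forces(c(a, 0, 0, a), at_walls, p)
  f <- a * 8                       # gain * spring length * activation
  expect_equal(wb$F_LW, f)
  expect_equal(wb$F_RW, -f)
  expect_equal(wb$F_Body, 2 * f)
  # one-sided push does not move the body
  wb <- wall_and_body_forces(c(a, 0, 0, 0), at_walls, p)
  expect_equal(wb$F_Body, 0)
})

test_that("plant stepping is a fixed point at rest and matches one Euler step", {
  p <- unit_plant()
  st <- plant_state()
  st2 <- step_plant(st, rep(0, 4), p)
  expect_equal(st2$ext_l, 0)
  expect_equal(st2$ext_r, 0)
  expect_equal(st2$body, 0)
  # closed form of one explicit step: displacement = f / viscosity * dt
  st3 <- step_plant(st, c(0.5, 0, 0, 0), p, dt = 0.01)
  f <- 0.5 * 4                      # activation * spring length * gain
  expect_equal(st3$ext_l, f / p$damping * 0.01)
})

test_that("body has stiction: sub-threshold pushes do not move it", {
  p <- unit_plant()
  at_walls <- plant_state(ext_l = 4, ext_r = 4)
  # |F_Body| = 0.4 x max muscle force (= gain * 8): a = 0.2 -> F_Body = 3.2
  st <- step_plant(at_walls, c(0.2, 0, 0, 0.2), p)
  expect_equal(st$body, 0)
  # above threshold (0.5 * 8 = 4): a = 0.3 -> F_Body = 4.8, body moves
  st <- step_plant(at_walls, c(0.3, 0, 0, 0.3), p)
  expect_equal(st$body, 4.8 / p$damping * p$dt)
})

test_that("limbs never exceed the anatomical stops under random drive", {
  p <- plant_params()
  st <- plant_state()
  set.seed(99)
  for (i in 1:500) {
    st <- step_plant(st, runif(4), p)
    expect_true(abs(st$ext_l) <= 4 + 1e-12)
    expect_true(abs(st$ext_r) <= 4 + 1e-12)
  }
})

test_that("step activation produces a monotonic overdamped approach", {
  p <- plant_params()
  st <- plant_state()
  xs <- numeric(300)
  for (i in seq_along(xs)) {
    st <- step_plant(st, c(0.6, 0, 0, 0), p)
    xs[i] <- st$ext_l
  }
  expect_true(all(diff(xs) >= 0))
  expect_true(all(xs <= 4))
})

test_that("gain calibration yields a ~2 s stop-to-stop traverse", {
  p <- plant_params()   # calibrated on construction
  traverse <- function(gain, ms = 1) {
    pp <- plant_params(gain = gain, muscle_strength = ms)
    st <- plant_state(ext_l = -4)
    t <- 0
    while (st$ext_l < 4 - 0.08 && t < 60) {
      st <- step_plant(st, c(1, 0, 0, 0), pp)
      t <- t + pp$dt
    }
    t
  }
  t1 <- traverse(p$gain)
  expect_gte(t1, 1.75)
  expect_lte(t1, 2.25)
  # doubling the gain strictly shortens the traverse
  expect_lt(traverse(2 * p$gain), t1)
})

test_that("at 10% strength a short twitch gives ~10% of the full response", {
  p <- plant_params()
  run <- function(ms) {
    pp <- plant_params(gain = p$gain, muscle_strength = ms)
    st <- plant_state()
    for (i in 1:3) st <- step_plant(st, c(1, 0, 0, 0), pp)  # 30 ms twitch
    st$ext_l
  }
  ratio <- run(0.1) / run(1)
  expect_equal(ratio, 0.1, tolerance = 0.05)
})
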