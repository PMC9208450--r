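test_that("twitch parameters are drawn from the stated uniform ranges", {
  cfg <- apg_config(p = 0.1, duration_range = c(50, 100))
  set.seed(11)
  ev <- replicate(10000, unlist(sample_twitch(cfg)[c("amplitude", "duration",
                                                     "gain")]))
  expect_true(all(ev["amplitude", ] >= 0 & ev["amplitude", ] <= 1))
  expect_true(all(ev["duration", ] >= 0.050 & ev["duration", ] <= 0.100))
  expect_true(all(ev["gain", ] >= 0.5 & ev["gain", ] <= 0.8))
  expect_equal(mean(ev["amplitude", ]), 0.5, tolerance = 0.01)
  set.seed(3); a <- sample_twitch(cfg)
  set.seed(3); b <- sample_twitch(cfg)
  expect_identical(a, b)
})

test_that("twitch waveform is the smoothed square pulse with decay truncation", {
  ev <- list(muscle = 1, onset = 1, amplitude = 0.8, duration = 0.5,
             gain = 0.6)
  expect_equal(twitch_waveform(ev, c(0, 0.5, 0.99)), rep(0, 3))
  # closed form of the rise: amplitude * (1 - (1-g)^n) after n steps
  n <- 1:10
  expect_equal(twitch_waveform(ev, 1 + (n - 1) * 0.01),
               0.8 * (1 - 0.4^n))
  # never exceeds the amplitude, decays to exactly zero after the tail
  t <- seq(0, 3, by = 0.01)
  w <- twitch_waveform(ev, t)
  expect_true(all(w <= 0.8 + 1e-12))
  expect_true(all(w[t > 2] == 0))
})

test_that("variant constraints hold at every step of generated drive", {
  n <- 60000   # 600 s
  set.seed(21)
  d_full <- generate_apg_drive(apg_config(p = 0.3), n)$drive
  expect_true(all(d_full >= 0 & d_full <= 1))
  expect_gt(sum(d_full > 0), 0)

  set.seed(22)
  d_nc <- generate_apg_drive(apg_config("no_cocontraction", p = 0.5), n)$drive
  expect_true(all(!(d_nc[, "LE"] > 0 & d_nc[, "LF"] > 0)))
  expect_true(all(!(d_nc[, "RF"] > 0 & d_nc[, "RE"] > 0)))

  set.seed(23)
  d_sym <- generate_apg_drive(apg_config("symmetrical_only", p = 0.3), n)$drive
  expect_true(all((d_sym[, "LE"] > 0) == (d_sym[, "RE"] > 0)))
  expect_true(all((d_sym[, "LF"] > 0) == (d_sym[, "RF"] > 0)))

  set.seed(24)
  d_ip <- generate_apg_drive(apg_config("in_phase_only", p = 0.3), n)$drive
  expect_true(all((d_ip[, "LE"] > 0) == (d_ip[, "RF"] > 0)))
  expect_true(all((d_ip[, "LF"] > 0) == (d_ip[, "RE"] > 0)))

  set.seed(25)
  expect_true(all(generate_apg_drive(apg_config(p = 0), n)$drive == 0))
})

test_that("drive generation is deterministic and long twitches stay in range", {
  set.seed(9); a <- generate_apg_drive(apg_config(p = 0.25), 20000)
  set.seed(9); b <- generate_apg_drive(apg_config(p = 0.25), 20000)
  expect_identical(a, b)
  set.seed(10)
  d <- generate_apg_drive(apg_config(p = 0.25,
                                     duration_range = c(950, 1000)), 50000)
  expect_true(all(d$drive >= 0 & d$drive <= 1))
  expect_true(all(d$events$duration >= 0.950 & d$events$duration <= 1.000))
})

test_that("coactivation probability increases monotonically with p", {
  frac_coactive <- function(p) {
    set.seed(77)
    d <- generate_apg_drive(apg_config(p = p), 100000)$drive
    mean(rowSums(d > 0) >= 2)
  }
  f <- vapply(c(0.1, 0.25, 0.5, 0.75), frac_coactive, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("phasic permutations enumerate all muscle subsets", {
  expect_equal(nrow(phasic_sequence(id = 0)), 0)
  sets <- lapply(0:15, function(i) sort(phasic_sequence(id = i)$muscle))
  expect_equal(length(unique(sets)), 16)
  expect_equal(sort(phasic_sequence(id = 15)$muscle), sort(MUSCLES))
  expect_error(phasic_sequence(id = 16), "0..15")
})

test_that("scripted probe pulse drives exactly the targeted motoneuron", {
  script <- phasic_sequence(muscles = "LE", onset = 0.5, amplitude = 1,
                            duration = 0.05, gain = 1)
  d <- apg_drive_from_script(script, 200)
  expect_true(all(d[, c("LF", "RF", "RE")] == 0))
  active <- which(d[, "LE"] > 0)
  expect_gte(length(active), 5)               # >= 50 ms
  expect_equal(d[active, "LE"], rep(1, length(active)))  # square, gain 1
})
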