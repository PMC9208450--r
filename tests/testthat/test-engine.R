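test_that("compiled core and pure-R reference engine agree", {
  cfg <- short_config(duration = 100)
  a <- run_simulation(cfg, seed = 7)
  b <- run_simulation_r(cfg, seed = 7)
  expect_equal(a$weights, b$weights, tolerance = 1e-12)
  for (nm in names(a$state)) {
    expect_equal(as.numeric(a$state[[nm]]), as.numeric(b$state[[nm]]),
                 tolerance = 1e-12, info = nm)
  }
})

test_that("runs are bit-identical under a fixed seed", {
  cfg <- short_config(duration = 200)
  a <- run_simulation(cfg, seed = 42)
  b <- run_simulation(cfg, seed = 42)
  expect_identical(a$weights, b$weights)
  expect_identical(a$state, b$state)
  c <- run_simulation(cfg, seed = 43)
  expect_false(identical(a$weights, c$weights))
})

test_that("no drive and zero weights leave the network untouched", {
  cfg <- short_config(duration = 100, apg = apg_config(p = 0))
  sim <- run_simulation(cfg, seed = 1, weights = matrix(0, 4, 4))
  expect_true(all(sim$weights == 0))
})

test_that("weights stay in [-1, 1] at every snapshot of a training run", {
  cfg <- sim_config(duration = 1000, snapshot_interval = 100,
                    apg = apg_config(p = 0.5))
  sim <- run_simulation(cfg, seed = 2)
  w <- as.matrix(sim$snapshots[, -1])
  expect_true(all(w >= -1 & w <= 1))
  expect_equal(nrow(sim$snapshots), 10)
  expect_equal(sim$snapshots$time_s, seq(100, 1000, by = 100))
})

test_that("weight summaries partition the matrix by functional relationship", {
  rel <- relationship_matrix()
  expect_equal(unname(table(rel)[c("homonymous", "antagonist", "in_phase",
                                   "mirror")]), rep(4L, 4), ignore_attr = TRUE)
  s <- summarize_weights(diag(4))
  expect_equal(s$mean[s$relationship == "homonymous"], 1)
  expect_equal(s$mean[s$relationship != "homonymous"], rep(0, 3))
  s2 <- summarize_weights(matrix(0.3, 4, 4))
  expect_equal(s2$mean, rep(0.3, 4))
  W <- diag(4)
  for (i in 1:4) W[i, spinloop:::IN_PHASE[i]] <- 0.5
  s3 <- summarize_weights(W)
  expect_equal(s3$mean, c(1, 0, 0.5, 0))
  expect_error(summarize_weights(matrix(0, 3, 3)))
})

test_that("snapshots round-trip losslessly and resuming reproduces a full run", {
  full <- run_simulation(sim_config(duration = 300, snapshot_interval = 100),
                         seed = 3)
  half <- run_simulation(sim_config(duration = 150, snapshot_interval = 50),
                         seed = 3)
  f <- tempfile(fileext = ".json")
  write_snapshot(half, f)
  snap <- read_snapshot(f)
  expect_identical(lapply(snap$state, as.numeric),
                   lapply(half$state, as.numeric))
  res <- resume_simulation(f, duration = 300)
  expect_identical(res$weights, full$weights)
  expect_identical(as.numeric(res$state$P), as.numeric(full$state$P))
})

test_that("corrupt or mismatched snapshot files are rejected with a message", {
  f <- tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(read_snapshot(f), "cannot parse")
  jsonlite::write_json(list(format = "other"), f, auto_unbox = TRUE)
  expect_error(read_snapshot(f), "not a spinloop snapshot")
  sim <- run_simulation(short_config(duration = 50), seed = 1)
  write_snapshot(sim, f)
  txt <- sub('"version":1', '"version":99', readLines(f))
  writeLines(txt, f)
  expect_error(read_snapshot(f), "version")
})

test_that("shunting playback attenuates phasic responses (leaky integration)", {
  # the attenuation property belongs to the fully shunting neuron (every
  # synapse, including the drive, adds to the denominator): the motoneuron
  # integrates its drive leakily, so routed responses are smaller than
  # open-loop playback of the same schedule
  script <- do.call(rbind, lapply(c(1, 4, 7), function(t0)
    phasic_sequence(muscles = c("LE", "RE"), onset = t0, amplitude = 0.9,
                    duration = 0.5, gain = 0.7)))
  open <- run_playback(script, network = FALSE, duration = 10,
                       apg_shunt = TRUE)
  net <- run_playback(script, weights = diag(4) * 0.2, network = TRUE,
                      duration = 10, apg_shunt = TRUE)
  expect_lt(max(net$traces$A_LE), max(open$traces$A_LE))
  expect_gt(max(net$traces$A_LE), 0)
})

test_that("recorded traces export to the documented CSV layout", {
  cfg <- short_config(duration = 10)
  sim <- run_simulation(cfg, seed = 1, record = TRUE)
  f <- tempfile(fileext = ".csv")
  out <- export_trace(sim, f)
  expect_true(file.exists(f))
  expect_equal(names(out),
               c("time_s", "x_L", "x_R", "body", paste0("L_", MUSCLES),
                 paste0("V_", MUSCLES), paste0("A_", MUSCLES)))
  expect_true(all(out[paste0("L_", MUSCLES)] >= 0.2 &
                  out[paste0("L_", MUSCLES)] <= 1))
  expect_error(export_trace(run_simulation(cfg, seed = 1), f), "record")
})

test_that("probe returns kinematics and flags and rejects nothing silently", {
  pr <- probe_reflex(diag(4), muscle_strength = 0.1)
  expect_type(pr$antagonist_response, "logical")
  expect_gt(pr$response_duration, 0)
  expect_gt(pr$peak_displacement, 0)
  # zero-amplitude pulse: no response anywhere
  pr0 <- probe_reflex(diag(4), muscle_strength = 0.1, amplitude = 0)
  expect_equal(pr0$peak_displacement, 0)
  expect_false(pr0$antagonist_response)
  expect_equal(pr0$response_duration, 0)
})
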