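test_that("identical seeds give bit-identical datasets", {
  cfg <- synthetic_config(n_neurons = 16, noise_sd = 1.5,
                          trials_per_condition = 2, seed = 33)
  d1 <- generate_population(cfg)
  d2 <- generate_population(cfg)
  expect_identical(d1$truth$W_true, d2$truth$W_true)
  for (s in c(1, 5, length(d1$sessions))) {
    expect_identical(d1$sessions[[s]]$trials[[1]]$rate,
                     d2$sessions[[s]]$trials[[1]]$rate)
    expect_identical(d1$sessions[[s]]$trials[[1]]$eye,
                     d2$sessions[[s]]$trials[[1]]$eye)
  }
  p1 <- generate_pulse_experiment(cfg)
  p2 <- generate_pulse_experiment(cfg)
  expect_identical(
    vapply(p1$sessions[[1]]$trials, function(t) t$pulse_onset, numeric(1)),
    vapply(p2$sessions[[1]]$trials, function(t) t$pulse_onset, numeric(1)))
  expect_identical(p1$sessions[[2]]$trials[[3]]$speed,
                   p2$sessions[[2]]$trials[[3]]$speed)
})

test_that("no planted ramp means zero preparatory modulation everywhere", {
  cfg <- synthetic_config(n_neurons = 16, noise_sd = 0, prep_amp_1 = 0,
                          prep_amp_2 = 0, subpop2_offset = 0,
                          trials_per_condition = 2, seed = 5)
  ds <- generate_population(cfg)
  pop <- build_pseudopopulation(ds$sessions)
  expect_equal(max(abs(pop$meta$prep_mod)), 0, tolerance = 1e-12)
})

test_that("noise-free eye velocity equals the planted readout applied to rates", {
  fx <- noiseless_dataset()
  E_pred <- fx$truth$W_true %*% fx$pop$N_8D
  expect_lt(max(abs(fx$pop$E - E_pred)), 1e-10)
})

test_that("fixation durations are uniform on the configured range", {
  cfg <- synthetic_config(n_neurons = 64, noise_sd = 0, include_eye = FALSE,
                          trials_per_condition = 12, trials_8dir = 12,
                          seed = 77)
  ds <- generate_population(cfg)
  durs <- unlist(lapply(ds$sessions, function(s)
    vapply(s$trials, function(tr) tr$motion_onset, numeric(1))))
  expect_gte(length(durs), 1e4)
  ks <- suppressWarnings(stats::ks.test(durs, "punif", 800, 1601))
  expect_gt(ks$p.value, 0.01)
})

test_that("pulse responses realize the planted gain exactly when noise is off", {
  cfg <- synthetic_config(noise_sd = 0, n_sessions = 2,
                          trials_per_session = 40,
                          gain_params = c(g0 = 1, a_dir = 0, b0 = 0, b1 = 0),
                          context_factors = c(fast = 1, slow = 1, control = 1),
                          saccade_rate = 0, seed = 12)
  pl <- generate_pulse_experiment(cfg)
  ex <- extract_pulse_responses(pl)
  expect_gt(ex$n_kept, 10)
  expect_equal(ex$responses$response, rep(5, ex$n_kept), tolerance = 1e-9)

  cfg2 <- synthetic_config(noise_sd = 0, n_sessions = 2,
                           trials_per_session = 60,
                           gain_params = c(g0 = 0.4, a_dir = 0, b0 = 1, b1 = 0),
                           context_factors = c(fast = 1, slow = 1, control = 1),
                           saccade_rate = 0, seed = 13)
  pl2 <- generate_pulse_experiment(cfg2)
  ex2 <- extract_pulse_responses(pl2)
  # peak = 5 * (0.4 + t) at every pulse time t (s); e.g. 5.0 deg/s at 600 ms
  expect_equal(ex2$responses$response,
               5 * (0.4 + ex2$responses$time_ms / 1000), tolerance = 1e-9)
})

test_that("ground truth is the exact planted parameter set", {
  fx <- noiseless_dataset()
  tr <- ground_truth(fx$ds)
  expect_identical(tr$W_true, fx$ds$truth$W_true)
  # planted angle is reproduced by the angle formula on the planted loadings
  expect_equal(tr$theta_true,
               subspace_angle(tr$prep_loadings, tr$purs_loadings))
  cfg <- synthetic_config(n_neurons = 16, frac_subpop2 = 0, noise_sd = 0,
                          trials_per_condition = 2, include_eye = FALSE,
                          seed = 2)
  ds <- generate_population(cfg)
  expect_true(all(ground_truth(ds)$subpop_labels == 1))
  expect_error(ground_truth(list(a = 1)), "not a dataset")
})

test_that("invalid block specifications are rejected", {
  expect_error(synthetic_config(block_specs = data.frame(
    direction = 30, speed = 15, contrast = 100, context = "control")),
    "45")
  expect_error(synthetic_config(n_neurons = 8), "n_neurons")
  expect_error(synthetic_config(frac_subpop2 = 1.2), "frac_subpop2")
})
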