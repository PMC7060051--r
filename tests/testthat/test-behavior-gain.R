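test_that("saccade detection finds inserted transients and nothing else", {
  quiet <- rep(0.5, 800) + 0.01 * sin(seq_len(800) / 40)
  expect_equal(nrow(detect_saccades(quiet)), 0)

  spik <- quiet
  spik[301:330] <- spik[301:330] + 200  # 30-ms, 200 deg/s transient
  iv <- detect_saccades(spik)
  expect_equal(nrow(iv), 1)
  expect_lte(iv[1, "from"], 300)
  expect_gte(iv[1, "to"], 329)

  # exactly at threshold: strict inequality, not detected
  thr <- rep(0, 500); thr[200:220] <- 30
  expect_equal(nrow(detect_saccades(thr, speed_threshold = 30,
                                    accel_threshold = 1e9)), 0)
  expect_error(detect_saccades(c(1, 2)), "3 samples")
})

test_that("pulse response is the windowed maximum and ignores outside peaks", {
  z <- list(speed = rep(0, 1200), pulse_onset = 600)
  expect_equal(pulse_response(z), 0)

  bump <- rep(0, 1200)
  bump[600 + 120 + 1] <- 2.5
  expect_equal(pulse_response(list(speed = bump, pulse_onset = 600)), 2.5)

  two <- rep(0, 1200)
  two[600 + 120 + 1] <- 1.1
  two[600 + 250 + 1] <- 9    # outside (pulse, pulse+200]
  expect_equal(pulse_response(list(speed = two, pulse_onset = 600)), 1.1)
  expect_error(pulse_response(list(speed = rep(0, 700), pulse_onset = 600)),
               "truncated")
})

test_that("gain slopes follow closed-form regression on constructed responses", {
  d <- data.frame(session = "s1", class = "same",
                  time_ms = c(600, 800, 1000, 1200),
                  response = 2.2)
  g <- gain_timecourse(d)
  expect_equal(g$slopes$slope, 0, tolerance = 1e-12)

  d2 <- data.frame(session = "s1", class = "same",
                   time_ms = seq(550, 1350, by = 100))
  d2$response <- 1 + 1.0 * d2$time_ms / 1000
  g2 <- gain_timecourse(d2)
  expect_equal(g2$slopes$slope, 1, tolerance = 1e-10)
  # binned means sit at bin centers
  expect_true(all(g2$binned$time_ms %in% seq(650, 1250, by = 200)))

  bad <- data.frame(session = "s1", class = "same", time_ms = 700,
                    response = 1)
  expect_error(gain_timecourse(bad), "slope undefined")
})

test_that("context effect reports means, d and the signed-rank test", {
  x <- c(2, 3, 2.5, 4)
  same <- context_effect(x, x)
  expect_true(same$degenerate)
  expect_equal(same$d, NA_real_)

  # simulation against the analytic effect size
  set.seed(19)
  m <- 0.6; s <- 0.4
  slow <- rnorm(500, 2.3, 0.5)
  fast <- slow + rnorm(500, m, s)
  ce <- context_effect(fast, slow)
  expect_equal(ce$d, m / s, tolerance = 0.1)
  expect_lt(ce$p, 1e-10)
  expect_equal(unname(ce$means["fast"] - ce$means["slow"]), m, tolerance = 0.1)
})

test_that("gain-rate regression matches proportional and two-point cases", {
  rates <- rbind(seq(10, 20, length.out = 5),
                 seq(40, 20, length.out = 5))
  gain <- 0.1 * rates[1, ]
  gr <- gain_rate_regression(gain, rates)
  expect_equal(unname(gr$slopes[1]), 0.1, tolerance = 1e-10)
  # two-point closed form
  g2 <- c(1, 2); r2 <- matrix(c(10, 30), 1)
  expect_equal(unname(gain_rate_regression(g2, r2)$slopes[1]), 1 / 20)
  expect_error(gain_rate_regression(1, matrix(1, 1, 1)), "2 fixation")
})

test_that("planted gain slopes are recovered exactly from noise-free sessions", {
  cfg <- synthetic_config(noise_sd = 0, n_sessions = 3, trials_per_session = 120,
                          saccade_rate = 0, seed = 29)
  pl <- generate_pulse_experiment(cfg)
  ex <- extract_pulse_responses(pl)
  rdir <- ex$responses[ex$responses$experiment == "direction", ]
  g <- gain_timecourse(rdir)
  gp <- cfg$gain_params
  planted <- c(same = 5 * (gp[["b0"]] + gp[["b1"]]),
               orthogonal = 5 * gp[["b0"]],
               opposite = 5 * (gp[["b0"]] - gp[["b1"]]))
  for (cl in names(planted)) {
    got <- g$by_class$mean_slope[g$by_class$class == cl]
    expect_equal(got, unname(planted[cl]), tolerance = 1e-6)
  }
})

test_that("saccade rejection removes all transient trials and no clean ones", {
  cfg <- synthetic_config(noise_sd = 0, n_sessions = 3, trials_per_session = 80,
                          saccade_rate = 0.2, seed = 30)
  pl <- generate_pulse_experiment(cfg)
  ex <- extract_pulse_responses(pl)
  n_sacc <- sum(vapply(pl$sessions, function(s)
    sum(vapply(s$trials, function(t) isTRUE(t$has_saccade), logical(1))),
    numeric(1)))
  n_pulse <- sum(vapply(pl$sessions, function(s)
    sum(vapply(s$trials, function(t) isTRUE(t$has_pulse), logical(1))),
    numeric(1)))
  expect_equal(ex$n_rejected, n_sacc)
  expect_equal(ex$n_kept, n_pulse - n_sacc)
})
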