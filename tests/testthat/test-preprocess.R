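test_that("trial averaging is the per-ms mean and respects ragged fixations", {
  t1 <- make_trial(rep(10, 1300), motion_onset = 1000)
  t2 <- make_trial(rep(20, 1300), motion_onset = 1000)
  ta <- trial_average(list(t1, t2), "fixation", c(0, 999))
  expect_equal(unique(ta$mean), 15)

  # durations 900 and 1500: samples beyond 900 ms come from one trial only
  a <- make_trial(seq_len(1250), motion_onset = 900)
  b <- make_trial(seq_len(1850) * 2, motion_onset = 1500)
  ta <- trial_average(list(a, b), "fixation", c(0, 1499))
  expect_equal(ta$n[1:900], rep(2L, 900))
  expect_equal(ta$n[901:1500], rep(1L, 600))
  expect_equal(ta$mean[5], (a$rate[5] + b$rate[5]) / 2)
  expect_equal(ta$mean[1200], b$rate[1200])

  one <- trial_average(list(a), "fixation", c(0, 899))
  expect_equal(one$mean, a$rate[1:900])

  # motion alignment
  tm <- trial_average(list(a, b), "motion", c(0, 99))
  expect_equal(tm$mean[1], (a$rate[901] + b$rate[1501]) / 2)
  expect_error(trial_average(list(), "fixation", c(0, 10)), "no trials")
})

test_that("gaussian smoothing preserves constants and matches direct convolution", {
  expect_equal(gaussian_smooth(rep(7.5, 300), 20), rep(7.5, 300))

  # unit impulse against a direct discrete convolution with renormalization
  x <- numeric(501); x[251] <- 1
  sm <- gaussian_smooth(x, 20)
  k <- dnorm(seq(-80, 80), sd = 20); k <- k / sum(k)
  expect_equal(sm[251], k[81], tolerance = 1e-12)
  direct <- convolve(x, rev(k), type = "open")[80 + seq_len(501)]
  expect_equal(sm, direct, tolerance = 1e-10)  # interior: full kernel support

  set.seed(2)
  y <- rnorm(100)
  expect_equal(gaussian_smooth(y, 0.01), y, tolerance = 1e-6)
  expect_error(gaussian_smooth(numeric(0), 20), "empty")
})

test_that("preferred direction is the weighted circular mean with QC flags", {
  w <- c(0, 0, 1, 0, 0, 0, 0, 0)  # weight at 90 deg
  expect_equal(preferred_direction(w)$direction, 90)
  w2 <- c(1, 0, 1, 0, 0, 0, 0, 0)  # equal at 0 and 90
  expect_equal(preferred_direction(w2)$direction, 45)
  unif <- preferred_direction(rep(1, 8))
  expect_false(unif$defined)
  expect_true(is.na(unif$direction))
  expect_error(preferred_direction(c(-1, rep(1, 7))), "nonnegative")
})

test_that("direction rotation re-keys tuning and preserves eye speed", {
  resp <- stats::setNames(as.list(1:8), DIR_GRID)
  rot <- rotate_directions(resp, 90)
  expect_equal(rot[["0"]], resp[["90"]])   # 90 becomes 0
  expect_equal(rot[["90"]], resp[["180"]]) # 180 becomes 90
  expect_equal(rotate_directions(resp, 0), resp[order(DIR_GRID)])
  # rotation by 90 then 270 composes to the identity
  expect_equal(rotate_directions(rotate_directions(resp, 90), 270), resp)
  expect_error(rotate_directions(stats::setNames(list(1), 30), 0), "45")

  eye <- matrix(rnorm(20), 2)
  rot_eye <- rotate_eye_velocity(eye, 135)
  expect_equal(sqrt(colSums(rot_eye^2)), sqrt(colSums(eye^2)))
  expect_equal(rotate_eye_velocity(matrix(c(1, 0), 2, 1), 90),
               matrix(c(0, -1), 2, 1), tolerance = 1e-12)
})

test_that("preparatory and pursuit modulation follow their window definitions", {
  ev <- list(motion_onset = 1000)
  flat <- rep(20, 1400)
  expect_equal(prep_modulation(flat, ev), 0)
  expect_equal(purs_modulation(flat, ev), 0)

  ramp <- 0.01 * (0:1399)
  expect_equal(prep_modulation(ramp, ev),
               mean(ramp[(900:999) + 1]) - mean(ramp[(151:250) + 1]))

  step <- c(rep(30, 300), rep(10, 1100))
  expect_lt(prep_modulation(step, ev), 0)

  two <- c(rep(10, 1000), rep(40, 400))
  expect_equal(purs_modulation(two, ev), 30)

  set.seed(8)
  noisy <- rnorm(1400, 15, 4)
  expect_equal(purs_modulation(noisy, ev),
               mean(noisy[(1051:1150) + 1]) - mean(noisy[(900:999) + 1]))

  # linearity on random traces
  x <- rnorm(1400); y <- rnorm(1400)
  expect_equal(prep_modulation(2 * x + 3 * y, ev),
               2 * prep_modulation(x, ev) + 3 * prep_modulation(y, ev))
  expect_equal(purs_modulation(2 * x + 3 * y, ev),
               2 * purs_modulation(x, ev) + 3 * purs_modulation(y, ev))
  expect_error(prep_modulation(flat, list(motion_onset = 300)), "350")
})

test_that("direction-group classification uses half-open 45-degree boundaries", {
  expect_equal(classify_direction_group(0, 0), "same")
  expect_equal(classify_direction_group(90, 0), "orthogonal")
  expect_equal(classify_direction_group(180, 0), "opposite")
  expect_equal(classify_direction_group(44.9, 0), "same")
  expect_equal(classify_direction_group(45, 0), "orthogonal")
  expect_equal(classify_direction_group(135, 0), "opposite")
  expect_equal(classify_direction_group(315, 0), "orthogonal")  # 45 exactly
  expect_equal(classify_direction_group(330, 0), "same")  # wraps
  expect_equal(classify_direction_group(NA, 0), "unclassified")
})

test_that("pseudo-population matrices satisfy the stated invariants", {
  pop <- noiseless_dataset()$pop
  expect_equal(ncol(pop$N_8D), 2000)
  expect_equal(ncol(pop$N_1D), 1400)
  expect_equal(ncol(pop$N_purs), 750)
  expect_lt(max(abs(rowMeans(pop$N_8D))), 1e-9)
  rngs <- apply(pop$N_8D, 1, function(v) diff(range(v)))
  expect_equal(rngs, rep(1, nrow(pop$N_8D)), tolerance = 1e-12)
  expect_equal(pop$N_1D[, 1], rep(0, nrow(pop$N_1D)))
  expect_equal(dim(pop$E), c(2, 2000))
})

test_that("range-degenerate units are excluded with a recorded reason", {
  ds <- noiseless_dataset()$ds
  sess <- ds$sessions
  # flatten one unit's rates entirely
  uid <- sess[[1]]$unit_id
  for (i in seq_along(sess)) {
    if (sess[[i]]$unit_id == uid) {
      sess[[i]]$trials <- lapply(sess[[i]]$trials, function(tr) {
        tr$rate[] <- 12; tr
      })
    }
  }
  pop <- build_pseudopopulation(sess)
  expect_true(uid %in% pop$excluded$unit_id)
  expect_false(uid %in% pop$meta$unit_id)
})
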