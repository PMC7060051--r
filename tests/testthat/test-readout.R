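test_that("ridgeless fit recovers planted weights exactly on noise-free data", {
  fx <- noiseless_dataset()
  m <- fit_readout(fx$pop$N_8D, fx$pop$E, lambda = 0)
  relerr <- sqrt(sum((m$W - fx$truth$W_true)^2) / sum(fx$truth$W_true^2))
  expect_lt(relerr, 1e-6)
})

test_that("single-unit ridge matches the closed-form normal equations", {
  set.seed(15)
  N <- matrix(rnorm(40), 1)
  E <- rbind(rnorm(40), rnorm(40))
  lam <- 1
  m <- fit_readout(N, E, lambda = lam)
  w_hand <- E %*% t(N) / (sum(N^2) + lam)  # (N N' + lam)^-1 scalar case
  expect_equal(m$W, w_hand, tolerance = 1e-10)
})

test_that("ridge shrinks monotonically and training residual grows with lambda", {
  set.seed(16)
  N <- matrix(rnorm(5 * 60), 5)
  E <- rbind(rnorm(60), rnorm(60))
  grid <- 10^seq(-2, 3, length.out = 8)
  norms <- resid <- numeric(length(grid))
  for (i in seq_along(grid)) {
    m <- fit_readout(N, E, lambda = grid[i])
    norms[i] <- sqrt(sum(m$W^2))
    resid[i] <- sum((E - m$W %*% N)^2)
  }
  expect_true(all(diff(norms) < 1e-12))
  expect_true(all(diff(resid) > -1e-12))
})

test_that("rank-deficient designs require regularization", {
  N <- matrix(rnorm(20), 2)[c(1, 1, 2), ]  # duplicated row
  E <- rbind(rnorm(10), rnorm(10))
  expect_error(fit_readout(N, E, lambda = 0), "rank deficient")
  expect_silent(m <- fit_readout(N, E, lambda = 0.1))
})

test_that("preparatory projection is linear and derives speed and direction", {
  fx <- noiseless_dataset()
  m <- fit_readout(fx$pop$N_8D, fx$pop$E, lambda = 0)
  N1 <- fx$pop$N_1D
  p1 <- predict_preparatory(m, N1)
  p2 <- predict_preparatory(m, 2 * N1)
  expect_equal(p2$PE, 2 * p1$PE, tolerance = 1e-10)
  expect_equal(p1$PS, sqrt(colSums(p1$PE^2)))

  z <- predict_preparatory(m, N1 * 0)
  expect_equal(max(abs(z$PE)), 0)
  expect_true(all(is.na(z$direction)))

  # direct-multiply oracle on a small random instance
  small <- matrix(rnorm(ncol(m$W) * 7), ncol(m$W))
  ps <- predict_preparatory(m, small)
  for (j in 1:7) {
    expect_equal(ps$PE[, j], as.vector(m$W %*% small[, j]), tolerance = 1e-12)
  }

  # 3-4-5 triangle
  toy <- structure(list(W = diag(2), lambda = 0, lag_ms = 25, n_units = 2),
                   class = "readout_model")
  pt <- predict_preparatory(toy, matrix(c(3, 4), 2, 1))
  expect_equal(pt$PS, 5)
  expect_equal(pt$direction, atan2(4, 3) * 180 / pi, tolerance = 1e-6)
})

test_that("cross-validation slope and r2 behave on constructed cases", {
  set.seed(17)
  N <- matrix(rnorm(3 * 50), 3)
  W <- matrix(rnorm(6), 2)
  E <- W %*% N
  m <- structure(list(W = W, lambda = 0, lag_ms = 25, n_units = 3),
                 class = "readout_model")
  cv <- cross_validate(m, N, E)
  expect_equal(unname(cv$slope), c(1, 1), tolerance = 1e-10)
  expect_equal(unname(cv$r2), c(1, 1), tolerance = 1e-10)
  # prediction = 2 x observation: slope of predicted on actual is 2
  cv2 <- cross_validate(m, N, E / 2)
  expect_equal(unname(cv2$slope), c(2, 2), tolerance = 1e-10)
  # zero-variance observed channel is flagged
  E0 <- E; E0[2, ] <- 0
  cv3 <- cross_validate(m, N, E0)
  expect_true(cv3$degenerate["v"])
})

test_that("single-trial bootstrap degenerates correctly and covers the truth", {
  # one identical trial per unit: the distribution collapses to the
  # deterministic projection
  W <- rbind(c(0.5, 0.2, -0.1), c(0, 0.3, 0.4))
  m <- structure(list(W = W, lambda = 0, lag_ms = 25, n_units = 3),
                 class = "readout_model")
  tp <- lapply(c(1, 2, 3), function(v)
    data.frame(duration = 1000, modulation = v))
  bt <- single_trial_bootstrap(tp, ranges = rep(1, 3), m, n_iter = 50, seed = 1)
  det <- W %*% c(1, 2, 3)
  expect_equal(unique(bt$speed_distribution), sqrt(sum(det^2)),
               tolerance = 1e-12)
  expect_equal(unique(round(bt$direction_distribution, 9)),
               round(atan2(det[2], det[1]) * 180 / pi, 9))

  # coverage: with iid noise around a planted modulation vector, the 95%
  # interval for speed covers the noise-free projection ~95% of the time
  set.seed(31)
  truth_mod <- c(2, 1, 3)
  det_speed <- sqrt(sum((W %*% truth_mod)^2))
  covered <- 0L
  for (r in 1:200) {
    tp <- lapply(truth_mod, function(v)
      data.frame(duration = runif(20, 800, 1600),
                 modulation = v + rnorm(20, 0, 0.3)))
    bt <- single_trial_bootstrap(tp, rep(1, 3), m, n_iter = 150,
                                 seed = 1000 + r)
    ci <- bt$ci95_speed
    if (det_speed >= ci[1] && det_speed <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered / 200, 0.85)
  expect_lte(covered / 200, 1)
  expect_error(single_trial_bootstrap(tp, rep(1, 3), m, n_iter = 1, seed = 1),
               "n_iter")
})
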