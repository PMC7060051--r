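test_that("spearman correlation handles monotone, tied and degenerate input", {
  up <- spearman_rank(1:8, (1:8)^2)
  expect_equal(up$rho, 1)
  dn <- spearman_rank(1:8, -(1:8))
  expect_equal(dn$rho, -1)

  # tied 6-point sample against a brute-force average-rank computation
  x <- c(1, 2, 2, 3, 4, 4)
  y <- c(5, 7, 6, 6, 9, 8)
  brute <- stats::cor(rank(x), rank(y))
  expect_equal(spearman_rank(x, y)$rho, brute)

  # exact-permutation p agrees with full enumeration done independently
  set.seed(4)
  xs <- rnorm(6); ys <- rnorm(6)
  res <- spearman_rank(xs, ys)
  rx <- rank(xs); ry <- rank(ys)
  enum <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in enum(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(enum(ry), function(p) stats::cor(rx, p), numeric(1))
  expect_equal(res$p, mean(abs(rhos) >= abs(res$rho) - 1e-12))

  cst <- spearman_rank(rep(1, 5), rnorm(5))
  expect_true(cst$degenerate)
  expect_true(is.na(cst$rho))
})

test_that("signed-rank exact p matches brute force over sign assignments", {
  set.seed(7)
  a <- rnorm(6); b <- rnorm(6)
  res <- wilcoxon_tests(a, b, paired = TRUE)
  d <- a - b
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  Vnull <- signs %*% r
  mu <- 6 * 7 / 4
  expect_equal(res$p, mean(abs(Vnull - mu) >= abs(V - mu) - 1e-12))
  expect_equal(res$statistic, V)

  same <- wilcoxon_tests(rnorm(5), b = NULL, paired = TRUE)
  expect_false(same$degenerate)
  zero <- wilcoxon_tests(rep(1, 6), rep(1, 6), paired = TRUE)
  expect_true(zero$degenerate)
})

test_that("rank-sum z/p agree with the base-R normal approximation", {
  set.seed(11)
  a <- rnorm(30, 0.5); b <- rnorm(25)
  res <- wilcoxon_tests(a, b, paired = FALSE)
  ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})

test_that("signed-rank normal approximation is calibrated under the null", {
  set.seed(13)
  p <- replicate(1000, wilcoxon_tests(rnorm(25), rnorm(25), paired = TRUE)$p)
  rej <- mean(p < 0.05)
  bounds <- stats::qbinom(c(0.005, 0.995), 1000, 0.05) / 1000
  expect_gte(rej, bounds[1])
  expect_lte(rej, bounds[2])
})

test_that("Cohen's d follows the closed form and is antisymmetric", {
  set.seed(5)
  b <- rnorm(40)
  d <- rnorm(40, mean = 0.75, sd = 0.71)
  a <- b + d
  expect_equal(cohens_d(a, b, paired = TRUE), mean(d) / sd(d))
  expect_equal(cohens_d(a, b, paired = TRUE), -cohens_d(b, a, paired = TRUE))
  expect_equal(cohens_d(b, b, paired = TRUE), NA_real_)
  # unpaired: pooled-sd formula
  x <- rnorm(20); y <- rnorm(25, 1)
  sp <- sqrt((19 * var(x) + 24 * var(y)) / 43)
  expect_equal(cohens_d(x, y, paired = FALSE), (mean(x) - mean(y)) / sp)
})

test_that("bootstrap interval uses interpolated order statistics", {
  expect_equal(bootstrap_ci(1:1000, 0.95), c(25.975, 975.025))
  expect_equal(bootstrap_ci(rep(3, 200), 0.95), c(3, 3))
  expect_equal(bootstrap_ci(1:50, 1), c(1, 50))
  expect_error(bootstrap_ci(numeric(0)), "empty")
})

test_that("dip statistic matches the brute-force unimodal-fit oracle", {
  set.seed(21)
  gens <- list(function(n) runif(n),
               function(n) c(rnorm(ceiling(n / 2), -2, 0.4),
                             rnorm(floor(n / 2), 2, 0.4)),
               function(n) rexp(n))
  for (n in c(4, 5, 6, 8)) {
    for (r in 1:6) {
      x <- round(gens[[(r %% 3) + 1]](n), 3)
      if (any(duplicated(x))) next
      expect_equal(dip_statistic(x), dip_lp_oracle(x), tolerance = 1e-6,
                   info = paste("n =", n, "rep", r))
    }
  }
})

test_that("dip statistic obeys the lower-bound law and affine invariance", {
  for (n in c(4, 8, 16)) {
    x <- seq_len(n)  # strictly monotone, evenly spaced: minimal dip
    expect_equal(dip_statistic(x), 1 / (2 * n))
  }
  set.seed(3)
  x <- rnorm(40)
  expect_equal(dip_statistic(x), dip_statistic(3.7 * x - 11), tolerance = 1e-12)
  expect_gte(dip_statistic(runif(50)), 1 / 100)
  expect_error(dip_statistic(1:3), "at least 4")
})

test_that("dip Monte-Carlo p-value is seeded and reproducible", {
  x <- c(rnorm(40, -2, 0.3), rnorm(40, 2, 0.3))
  d1 <- hartigan_dip(x, n_null = 200, seed = 9)
  d2 <- hartigan_dip(x, n_null = 200, seed = 9)
  expect_identical(d1$p, d2$p)
  expect_lt(d1$p, 0.05)  # strongly bimodal
  uni <- hartigan_dip(runif(80), n_null = 200, seed = 9)
  expect_gt(uni$p, 0.05)
})
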