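test_that("population PCA matches an independent SVD and handles rank-1 input", {
  r1 <- outer(c(1, -2, 3, 0.5, 2), seq(0, 1, length.out = 9))
  p <- pca_population(r1)
  expect_equal(p$variance_fractions[1], 1, tolerance = 1e-10)

  set.seed(23)
  X <- matrix(rnorm(35), 5, 7)
  p <- pca_population(X)
  # oracle: prcomp on the transposed, identically preprocessed matrix
  rng <- apply(X, 1, function(v) diff(range(v)))
  Xn <- X / rng; Xn <- Xn - rowMeans(Xn)
  ref <- prcomp(t(Xn), center = FALSE)
  k <- ncol(p$components)
  expect_equal(abs(p$components), abs(ref$rotation[, 1:k]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(p$variance_fractions[1:k],
               (ref$sdev^2 / sum(ref$sdev^2))[1:k], tolerance = 1e-8)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-8)
  expect_true(all(abs(crossprod(p$components) - diag(k)) < 1e-8))
  expect_error(pca_population(matrix(1, 4, 6)), "no variance")
})

test_that("subspace angle follows the arccos formula with sign symmetries", {
  v <- rnorm(10)
  expect_equal(subspace_angle(v, v), 0)
  expect_equal(subspace_angle(c(1, 0), c(0, 1)), 90)
  expect_equal(subspace_angle(c(1, 0), c(-1, 1) / sqrt(2)), 135)
  w <- rnorm(10)
  th <- subspace_angle(v, w)
  expect_equal(subspace_angle(-v, -w), th, tolerance = 1e-10)
  expect_equal(subspace_angle(-v, w), 180 - th, tolerance = 1e-10)
  expect_error(subspace_angle(rep(0, 5), rnorm(5)), "zero vector")
})

test_that("bootstrap angle is near zero for identical prep/pursuit loadings", {
  set.seed(41)
  n <- 168  # 21 per bin
  load <- rnorm(n)
  ramp <- seq(0, 1, length.out = 300)
  pop <- list(N_prep = outer(load, ramp) + matrix(rnorm(n * 300, 0, 0.01), n),
              N_purs = outer(load, ramp) + matrix(rnorm(n * 300, 0, 0.01), n),
              meta = data.frame(rel_bin = rep(DIR_GRID, length.out = n)))
  bs <- bootstrap_subspace(pop, n_iter = 100, group_size = 20, seed = 2)
  expect_lt(bs$mean_angle, 5)
  expect_lt(bs$p_vs_90, 0.05)
})

test_that("bootstrap recovers a planted 60-degree loading angle", {
  cfg <- synthetic_config(n_neurons = 176, noise_sd = 2,
                          trials_per_condition = 2, trials_8dir = 1,
                          include_eye = FALSE, theta_target = 60, seed = 91)
  ds <- generate_population(cfg)
  pop <- build_pseudopopulation(ds$sessions)
  tr <- ground_truth(ds)
  bs <- bootstrap_subspace(pop, n_iter = 300, group_size = 20, seed = 7)
  expect_gte(tr$theta_true, bs$ci95[1] - 3)
  expect_lte(tr$theta_true, bs$ci95[2] + 3)
  expect_lt(abs(bs$mean_angle - tr$theta_true), 4)
})

test_that("bootstrap PC1s equal full-sample PCA when bins are exhausted", {
  fx <- noisy_dataset()  # 160 rows, exactly 20 per bin
  pop <- fx$pop
  bs <- bootstrap_subspace(pop, n_iter = 2, group_size = 20, seed = 3)
  # sampling 20 without replacement from bins of 20 uses every row
  expect_equal(bs$angle_distribution[1], bs$angle_distribution[2])
  p1 <- pca_population(pop$N_prep)
  p2 <- pca_population(pop$N_purs)
  expect_equal(bs$mean_angle,
               subspace_angle(p1$components[, 1], p2$components[, 1]),
               tolerance = 1e-4)
})

test_that("small relative-direction bins raise a named error", {
  fx <- noisy_dataset()
  pop <- fx$pop
  expect_error(bootstrap_subspace(pop, n_iter = 5, group_size = 21, seed = 1),
               "fewer than 21")
})

test_that("loading-ratio split recovers planted subpopulation labels", {
  expect_equal(loading_ratio_split(c(0.5, 2, 1e-3)), c(1L, 1L, 1L))
  expect_equal(loading_ratio_split(c(-1, 0, NA)), c(2L, 2L, NA))

  cfg <- synthetic_config(n_neurons = 176, frac_subpop2 = 0.3,
                          subpop2_offset = 0, noise_sd = 0.5,
                          trials_per_condition = 2, trials_8dir = 1,
                          include_eye = FALSE, seed = 55)
  ds <- generate_population(cfg)
  pop <- build_pseudopopulation(ds$sessions)
  tr <- ground_truth(ds)
  bs <- bootstrap_subspace(pop, n_iter = 200, group_size = 20, seed = 9)
  lab <- loading_ratio_split(bs$mean_loading_ratios)
  # rows whose planted ramp amplitude is zero carry no label information
  informative <- which(abs(tr$prep_amplitudes) > 1e-9 & !is.na(lab))
  agree <- mean(lab[informative] == tr$subpop_labels[informative])
  expect_gt(agree, 0.95)
})

test_that("subpopulation analysis separates planted response classes", {
  # pure subpopulation 1: preparatory and pursuit modulation correlate
  cfg1 <- synthetic_config(n_neurons = 80, frac_subpop2 = 0, noise_sd = 1,
                           trials_per_condition = 2, seed = 66)
  ds1 <- generate_population(cfg1)
  pop1 <- build_pseudopopulation(ds1$sessions)
  sp <- subpopulation_analysis(pop1, rep(1L, nrow(pop1$meta)),
                               group_size = 5, n_iter = 50, seed = 4,
                               lambda = 1e-4)
  expect_gt(sp$subpop1$prep_purs_correlation$rho, 0.3)

  # direction-uniform subpopulation-2 gain: the preparatory readout
  # prediction is an order of magnitude weaker than a directionally tuned
  # ramp of the same amplitude
  cfg2 <- synthetic_config(n_neurons = 80, frac_subpop2 = 1, prep_amp_2 = 0,
                           subpop2_offset = 5, noise_sd = 1,
                           trials_per_condition = 3, seed = 67)
  ds2 <- generate_population(cfg2)
  pop2 <- build_pseudopopulation(ds2$sessions)
  sp2 <- subpopulation_analysis(pop2, rep(2L, nrow(pop2$meta)),
                                group_size = 5, n_iter = 200, seed = 5,
                                lambda = 1e-4)
  cfg3 <- synthetic_config(n_neurons = 80, frac_subpop2 = 0, prep_amp_1 = 5,
                           noise_sd = 1, trials_per_condition = 3, seed = 67)
  ds3 <- generate_population(cfg3)
  pop3 <- build_pseudopopulation(ds3$sessions)
  sp3 <- subpopulation_analysis(pop3, rep(1L, nrow(pop3$meta)),
                                group_size = 5, n_iter = 200, seed = 5,
                                lambda = 1e-4)
  h_uniform <- abs(mean(sp2$subpop2$single_trial$h_distribution))
  h_tuned <- abs(mean(sp3$subpop1$single_trial$h_distribution))
  expect_lt(h_uniform, 0.2 * h_tuned)
})
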