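# Principal-component geometry of the preparatory and pursuit epochs:
# epoch-wise PCA, the angle between first components, the bootstrap that
# resamples balanced pseudo-populations, loading ratios and the
# subpopulation decomposition they define.

# row preprocessing shared by all PCA entry points: normalize each row to
# unit range, then center each row on its mean. Rows with ~zero range are
# set to zero and flagged rather than amplified.
.pca_preprocess <- function(mat) {
  rng <- apply(mat, 1, function(v) diff(range(v)))
  med <- if (any(rng > 0)) stats::median(rng[rng > 0]) else 0
  flat <- !is.finite(rng) | rng < 1e-9 * max(med, .Machine$double.eps)
  sc <- ifelse(flat, 1, rng)
  x <- mat / sc
  x <- x - rowMeans(x)
  x[flat, ] <- 0
  list(x = x, flat = flat)
}

#' Principal component analysis of a population matrix
#'
#' Rows (units) are normalized to unity range and centered on their means;
#' components are the principal directions in unit space, ordered by
#' explained variance. Each component is oriented so that the projection of
#' the population activity onto it is nonnegative at the final sample.
#'
#' @param mat units x time matrix.
#' @param n_components number of components to retain (default all).
#' @return object of class `subspace_result`: `components` (units x k,
#'   orthonormal columns), `variance_fractions`, `projections` (k x time),
#'   `flat_rows` (indices of range-degenerate rows, loading 0).
#' @export
pca_population <- function(mat, n_components = NULL) {
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need at least a 2 x 2 matrix")
  pp <- .pca_preprocess(mat)
  if (all(pp$x == 0)) stop("matrix has no variance after preprocessing")
  sv <- svd(pp$x)
  k <- n_components %||% sum(sv$d > sv$d[1] * 1e-12)
  k <- min(k, length(sv$d))
  U <- sv$u[, seq_len(k), drop = FALSE]
  # orientation: projection time course nonnegative at the final sample
  fin <- as.vector(t(U) %*% pp$x[, ncol(pp$x)])
  flip <- ifelse(fin < 0, -1, 1)
  U <- sweep(U, 2, flip, "*")
  structure(list(
    components = U,
    variance_fractions = sv$d^2 / sum(sv$d^2),
    projections = t(U) %*% pp$x,
    flat_rows = which(pp$flat)),
    class = "subspace_result")
}

#' Angle between two loading vectors
#'
#' `arccos` of the normalized dot product, in degrees in [0, 180].
#'
#' @param v1,v2 nonzero numeric vectors of equal length.
#' @return angle in degrees.
#' @export
subspace_angle <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must have equal length")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-300 || n2 < 1e-300) stop("zero vector has no direction")
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

# leading eigenvector of a symmetric PSD matrix by power iteration with a
# deterministic start; falls back to eigen() if convergence stalls
.pc1_power <- function(G, start) {
  u <- start
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) u <- rep(1, nrow(G)) else u <- u / nu
  prev <- u
  for (i in 1:200) {
    u <- G %*% u
    nu <- sqrt(sum(u^2))
    if (nu < 1e-300) break
    u <- as.vector(u) / nu
    if (max(abs(abs(u) - abs(prev))) < 1e-8 && i >= 5) return(u)
    prev <- u
  }
  eigen(G, symmetric = TRUE)$vectors[, 1]
}

#' Bootstrap of the preparatory-vs-pursuit subspace angle
#'
#' Per iteration, `group_size` rows are drawn without replacement from each
#' of the eight relative-direction bins (a balanced pseudo-population), the
#' first preparatory and pursuit principal components are computed for that
#' sample, and the angle between them and the per-row loading ratios
#' `PC_Prep1 / PC_Purs1` are recorded.
#'
#' @param pop a `pseudopopulation` (uses `N_prep`, `N_purs`,
#'   `meta$rel_bin`), or a list with those fields.
#' @param n_iter bootstrap iterations (default 1000).
#' @param group_size rows per relative-direction bin (default 20).
#' @param seed integer seed.
#' @return list with `angle_distribution`, `mean_angle`, `ci95`,
#'   `p_vs_0`, `p_vs_90`, `mean_loading_ratios` (per row, `NA` when never
#'   sampled or always degenerate), `n_sampled` per row.
#' @export
bootstrap_subspace <- function(pop, n_iter = 1000, group_size = 20,
                               seed = 1) {
  rel <- pop$meta$rel_bin
  bins <- split(seq_along(rel), factor(rel, levels = DIR_GRID))
  short <- names(bins)[vapply(bins, length, integer(1)) < group_size]
  if (length(short) > 0) {
    stop(sprintf("relative-direction bin(s) %s have fewer than %d rows",
                 paste(short, collapse = ", "), group_size))
  }
  pp <- .pca_preprocess(pop$N_prep)
  pu <- .pca_preprocess(pop$N_purs)
  Gp <- tcrossprod(pp$x)
  Gu <- tcrossprod(pu$x)
  fp <- pp$x[, ncol(pp$x)]
  fu <- pu$x[, ncol(pu$x)]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nr <- length(rel)
  angles <- numeric(n_iter)
  ratio_sum <- numeric(nr); ratio_n <- integer(nr); samp_n <- integer(nr)
  for (it in seq_len(n_iter)) {
    idx <- unlist(lapply(bins, function(b) b[sample.int(length(b), group_size)]),
                  use.names = FALSE)
    up <- .pc1_power(Gp[idx, idx], fp[idx])
    uu <- .pc1_power(Gu[idx, idx], fu[idx])
    if (sum(up * fp[idx]) < 0) up <- -up
    if (sum(uu * fu[idx]) < 0) uu <- -uu
    angles[it] <- subspace_angle(up, uu)
    tolr <- 1e-3 * sqrt(mean(uu^2))
    ok <- abs(uu) >= tolr
    ratio_sum[idx[ok]] <- ratio_sum[idx[ok]] + up[ok] / uu[ok]
    ratio_n[idx[ok]] <- ratio_n[idx[ok]] + 1L
    samp_n[idx] <- samp_n[idx] + 1L
  }
  two_sided_p <- function(theta0) {
    max(2 * min(mean(angles <= theta0), mean(angles >= theta0)), 1 / n_iter)
  }
  list(angle_distribution = angles,
       mean_angle = mean(angles),
       ci95 = bootstrap_ci(angles, 0.95),
       p_vs_0 = two_sided_p(0),
       p_vs_90 = two_sided_p(90),
       mean_loading_ratios = ifelse(ratio_n > 0, ratio_sum / pmax(ratio_n, 1L),
                                    NA_real_),
       n_sampled = samp_n,
       n_iter = n_iter, group_size = group_size, seed = seed)
}

#' Split units into subpopulations by loading-ratio sign
#'
#' Label 1 for positive mean loading ratio, label 2 for non-positive;
#' `NA` ratios (pursuit loading below tolerance in every sampled iteration)
#' stay unassigned.
#'
#' @param mean_loading_ratios per-row mean `PC_Prep1 / PC_Purs1` ratios.
#' @return integer labels (1, 2, or `NA`).
#' @export
loading_ratio_split <- function(mean_loading_ratios) {
  ifelse(is.na(mean_loading_ratios), NA_integer_,
         ifelse(mean_loading_ratios > 0, 1L, 2L))
}

#' Compare the two loading-ratio subpopulations
#'
#' For each label: the bootstrap subspace angle (omitted with a warning when
#' some relative-direction bin has fewer rows than `group_size`), the
#' Spearman correlation between preparatory and pursuit modulation, the
#' normalized preparatory modulation by relative-direction group, and a
#' readout model refit on that subpopulation alone with its preparatory
#' prediction and single-trial bootstrap.
#'
#' @param pop a `pseudopopulation`.
#' @param labels integer labels from [loading_ratio_split()].
#' @param group_size rows per bin for the per-subpopulation bootstrap.
#' @param n_iter bootstrap iterations.
#' @param seed integer seed.
#' @param lambda ridge penalty for the refit (`NULL` = GCV).
#' @return list keyed `subpop1`, `subpop2`; each entry has `n`, `angle`
#'   (or `NULL`), `prep_purs_correlation`, `direction_profile`,
#'   `cross_validation`, `prep_prediction`, `single_trial`.
#' @export
subpopulation_analysis <- function(pop, labels, group_size = 5,
                                   n_iter = 1000, seed = 1, lambda = NULL) {
  out <- list()
  for (lab in 1:2) {
    sel <- which(!is.na(labels) & labels == lab)
    if (length(sel) < 4) {
      out[[paste0("subpop", lab)]] <- list(n = length(sel))
      next
    }
    sub <- list(
      N_8D = pop$N_8D[sel, , drop = FALSE],
      N_1D = pop$N_1D[sel, , drop = FALSE],
      N_prep = pop$N_prep[sel, , drop = FALSE],
      N_purs = pop$N_purs[sel, , drop = FALSE],
      N_purs_cv = pop$N_purs_cv[sel, , drop = FALSE],
      meta = pop$meta[sel, , drop = FALSE])
    ang <- tryCatch(
      bootstrap_subspace(sub, n_iter = n_iter, group_size = group_size,
                         seed = child_seed(seed, lab)),
      error = function(e) {
        warning(sprintf("subpopulation %d: angle omitted (%s)", lab,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    rho <- spearman_rank(sub$meta$prep_mod, sub$meta$purs_mod)
    prof <- tapply(sub$meta$prep_mod / sub$meta$range,
                   factor(sub$meta$direction_group,
                          levels = c("same", "orthogonal", "opposite")),
                   mean)
    model <- fit_readout(sub$N_8D, pop$E, lambda = lambda)
    cv <- if (!is.null(pop$E_purs)) {
      cross_validate(model, sub$N_purs_cv, pop$E_purs)
    } else NULL
    pred <- predict_preparatory(model, sub$N_1D)
    st <- single_trial_bootstrap(pop$trial_prep[sel], sub$meta$range, model,
                                 n_iter = n_iter,
                                 seed = child_seed(seed, 10 + lab))
    out[[paste0("subpop", lab)]] <- list(
      n = length(sel), angle = ang, prep_purs_correlation = rho,
      direction_profile = prof, cross_validation = cv,
      prep_prediction = pred, single_trial = st, model = model)
  }
  out
}

#' @export
print.subspace_result <- function(x, ...) {
  vf <- x$variance_fractions
  cat(sprintf("subspace_result: %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              ncol(x$components), 100 * vf[1],
              if (length(vf) > 1) 100 * vf[2] else NA))
  invisible(x)
}
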