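# The optimal linear model from population firing rate to eye velocity:
# ridge fit on the 8-direction block, cross-validation on the held-out
# single-direction block, projection of preparatory activity through the
# fitted weights, and the single-trial bootstrap of preparatory predictions.

#' Fit the linear readout from population rate to eye velocity
#'
#' Solves `min ||E - W N||^2 + lambda ||W||^2` in closed form through the
#' singular value decomposition of `N`. With `lambda = NULL` the penalty is
#' chosen by generalized cross-validation over a logarithmic grid
#' `10^-4 ... 10^2` in units of the mean squared singular value.
#'
#' @param N units x T rate-modulation matrix (rows mean-centered,
#'   range-normalized).
#' @param E 2 x T eye-velocity matrix (deg/s), columns matched to `N` after
#'   the behavioral lag shift.
#' @param lambda ridge penalty (>= 0) or `NULL` for GCV selection.
#' @param lag_ms behavioral lag recorded with the model (metadata).
#' @param smoothing_sigma_ms the Gaussian-smoothing sd applied upstream;
#'   GCV counts effective samples as `T / (2 sqrt(pi) sigma)` because the
#'   smoothed residuals are autocorrelated over that width.
#' @return object of class `readout_model`: `W` (2 x units), `lambda`,
#'   `lag_ms`, `weight_magnitudes` (per-unit Euclidean norm of the weight
#'   pair), `gcv` (grid and scores when GCV was used).
#' @export
fit_readout <- function(N, E, lambda = NULL, lag_ms = 25,
                        smoothing_sigma_ms = 20) {
  if (ncol(N) != ncol(E)) stop("column counts of N and E must match")
  if (nrow(E) != 2) stop("E must have 2 rows (horizontal, vertical)")
  sv <- svd(N)
  d <- sv$d
  tol <- max(dim(N)) * max(d) * .Machine$double.eps
  r <- sum(d > tol)
  gcv_info <- NULL
  if (is.null(lambda)) {
    # effective sample count: smoothing correlates neighboring samples over
    # ~2 sqrt(pi) sigma ms, so plain GCV would badly under-penalize
    rho <- max(1, 2 * sqrt(pi) * smoothing_sigma_ms)
    Teff <- ncol(N) / rho
    EV <- E %*% sv$v  # 2 x ncol(v)
    grid <- 10^seq(-4, 2, length.out = 25) * mean(d^2)
    scores <- vapply(grid, function(l) {
      f <- d^2 / (d^2 + l)
      # residual sum of squares of the ridge fit, via the SVD
      rss <- sum((EV * rep(1 - f, each = 2))^2) +
        (sum(E^2) - sum(EV^2))
      edf <- sum(f)
      if (edf >= Teff) return(Inf)
      (rss / rho) / (Teff * (1 - edf / Teff)^2)
    }, numeric(1))
    lambda <- grid[which.min(scores)]
    gcv_info <- list(grid = grid, scores = scores, t_eff = Teff)
  }
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0 && r < nrow(N)) {
    stop("rate matrix is rank deficient; regularization required (lambda > 0)")
  }
  keep <- seq_len(if (lambda == 0) r else length(d))
  shrink <- d[keep] / (d[keep]^2 + lambda)
  W <- E %*% sv$v[, keep, drop = FALSE] %*%
    (shrink * t(sv$u[, keep, drop = FALSE]))
  structure(list(W = W, lambda = lambda, lag_ms = lag_ms,
                 weight_magnitudes = sqrt(colSums(W^2)),
                 gcv = gcv_info, n_units = nrow(N)),
            class = "readout_model")
}

#' Cross-validate a readout model on held-out data
#'
#' Regresses the model's predicted velocity on the observed velocity across
#' all held-out time points, separately for the horizontal and vertical
#' channels.
#'
#' @param model a `readout_model`.
#' @param N_heldout units x T held-out rate matrix (normalized with the
#'   fitting ranges).
#' @param E_observed 2 x T observed eye velocity.
#' @return list with `slope` and `r2` (named h/v; `NA` with
#'   `degenerate = TRUE` entries when the observed channel has zero
#'   variance) and the predictions `P`.
#' @export
cross_validate <- function(model, N_heldout, E_observed) {
  if (nrow(N_heldout) != ncol(model$W)) stop("unit count mismatch with W")
  P <- model$W %*% N_heldout
  out <- lapply(1:2, function(ch) {
    a <- E_observed[ch, ]; p <- P[ch, ]
    va <- stats::var(a)
    if (!is.finite(va) || va < 1e-12 * max(stats::var(p), 1e-12)) {
      return(list(slope = NA_real_, r2 = NA_real_, degenerate = TRUE))
    }
    list(slope = stats::cov(a, p) / va, r2 = stats::cor(a, p)^2,
         degenerate = FALSE)
  })
  list(slope = c(h = out[[1]]$slope, v = out[[2]]$slope),
       r2 = c(h = out[[1]]$r2, v = out[[2]]$r2),
       degenerate = c(h = out[[1]]$degenerate, v = out[[2]]$degenerate),
       P = P)
}

#' Project preparatory activity through the readout
#'
#' `PE = W N_1D`: predicted eye velocity per millisecond of fixation, with
#' predicted speed (vector norm) and direction (two-argument arctangent,
#' degrees in [-180, 180); undefined where the speed is ~0).
#'
#' @param model a `readout_model`.
#' @param N_1D units x T preparatory matrix normalized with the fitting
#'   ranges and zeroed at its first retained sample.
#' @return object of class `eye_prediction`: `PE` (2 x T), `PS` (length T),
#'   `direction` (length T, `NA` where undefined).
#' @export
predict_preparatory <- function(model, N_1D) {
  if (nrow(N_1D) != ncol(model$W)) stop("unit count mismatch with W")
  PE <- model$W %*% N_1D
  PS <- sqrt(colSums(PE^2))
  dir <- ifelse(PS > 1e-12, wrap180(atan2(PE[2, ], PE[1, ]) * 180 / pi),
                NA_real_)
  structure(list(PE = PE, PS = PS, direction = dir),
            class = "eye_prediction")
}

#' Single-trial bootstrap of preparatory predictions
#'
#' Per iteration: pick a 100-ms fixation-duration bin, sample one
#' duration-matched trial per unit, normalize the per-trial preparatory
#' modulations to the 8-direction ranges, apply the readout, and record the
#' predicted direction and speed. Empty bins for a unit are widened in 100-ms
#' steps (counted in `n_widened`).
#'
#' @param trial_prep list (one element per unit/row) of data frames with
#'   columns `duration` (ms) and `modulation` (spikes/s).
#' @param ranges per-row normalization ranges (spikes/s).
#' @param model a `readout_model`.
#' @param n_iter number of bootstrap iterations (>= 2).
#' @param seed integer seed.
#' @param bin_ms fixation-duration bin width (default 100 ms).
#' @return list with `direction_distribution`, `speed_distribution`,
#'   `mean_direction` (circular mean, deg), `mean_speed`, `ci95_direction`,
#'   `ci95_speed`, `n_widened`.
#' @export
single_trial_bootstrap <- function(trial_prep, ranges, model, n_iter = 1000,
                                   seed = 1, bin_ms = 100) {
  if (n_iter < 2) stop("n_iter must be >= 2")
  nu <- length(trial_prep)
  if (nu != ncol(model$W)) stop("unit count mismatch with W")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  durs <- unlist(lapply(trial_prep, function(d) d$duration))
  lo <- floor(min(durs) / bin_ms) * bin_ms
  hi <- ceiling((max(durs) + 1) / bin_ms) * bin_ms
  breaks <- seq(lo, hi, by = bin_ms)
  nb <- length(breaks) - 1L
  # precompute per-unit trial indices per bin
  bins <- lapply(trial_prep, function(d) {
    b <- findInterval(d$duration, breaks, rightmost.closed = TRUE)
    split(seq_len(nrow(d)), factor(b, levels = seq_len(nb)))
  })
  n_widened <- 0L
  dirs <- numeric(n_iter); spd <- numeric(n_iter)
  hh <- numeric(n_iter); vv <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    b <- sample.int(nb, 1)
    v <- numeric(nu)
    for (u in seq_len(nu)) {
      cand <- bins[[u]][[b]]
      w <- 0L
      while (length(cand) == 0) {
        w <- w + 1L
        sel <- max(1, b - w):min(nb, b + w)
        cand <- unlist(bins[[u]][sel])
        if (w > nb) stop("unit has no trials at all")
      }
      if (w > 0) n_widened <- n_widened + 1L
      j <- cand[sample.int(length(cand), 1)]
      v[u] <- trial_prep[[u]]$modulation[j] / ranges[u]
    }
    pe <- model$W %*% v
    dirs[it] <- wrap180(atan2(pe[2], pe[1]) * 180 / pi)
    spd[it] <- sqrt(sum(pe^2))
    hh[it] <- pe[1]; vv[it] <- pe[2]
  }
  list(direction_distribution = dirs, speed_distribution = spd,
       h_distribution = hh, v_distribution = vv,
       ci95_h = bootstrap_ci(hh, 0.95), ci95_v = bootstrap_ci(vv, 0.95),
       mean_direction = wrap180(circ_mean_deg(dirs)),
       mean_speed = mean(spd),
       ci95_direction = bootstrap_ci(dirs, 0.95),
       ci95_speed = bootstrap_ci(spd, 0.95),
       n_widened = n_widened)
}

#' @export
print.readout_model <- function(x, ...) {
  cat(sprintf("readout_model: %d units, lambda = %.4g, lag = %d ms\n",
              x$n_units, x$lambda, x$lag_ms))
  invisible(x)
}
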