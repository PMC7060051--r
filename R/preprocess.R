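# Trial averaging, smoothing, direction handling, modulation measures, and
# assembly of the rotated, normalized pseudo-population matrices.
#
# Conventions: all traces are sampled at 1 kHz; sample 1 of every trace is the
# millisecond of fixation onset, so time t ms maps to index t + 1. Eye
# velocity is a 2 x T matrix (rows: horizontal, vertical; deg/s).

#' Trial-averaged firing rate
#'
#' Per-millisecond mean across trials, either aligned to fixation onset (each
#' trial contributes only up to its own motion onset, so late samples average
#' over fewer trials) or to motion onset.
#'
#' @param trials list of trial records (fields `rate`, `motion_onset`).
#' @param align_event `"fixation"` or `"motion"`.
#' @param window_ms inclusive `c(from, to)` in ms relative to the alignment
#'   event.
#' @return list with `mean` (rate trace, `NA` where no trial contributes) and
#'   `n` (contributing trials per ms).
#' @export
trial_average <- function(trials, align_event = "fixation", window_ms) {
  if (!align_event %in% c("fixation", "motion")) {
    stop("align_event must be 'fixation' or 'motion'")
  }
  if (length(trials) == 0) stop("no trials to average")
  nt <- window_ms[2] - window_ms[1] + 1
  acc <- numeric(nt)
  cnt <- integer(nt)
  for (tr in trials) {
    if (align_event == "fixation") {
      tt <- window_ms[1]:window_ms[2]
      keep <- tt >= 0 & tt < tr$motion_onset  # only up to this trial's motion onset
      idx <- tt[keep] + 1L
    } else {
      tt <- tr$motion_onset + (window_ms[1]:window_ms[2])
      keep <- tt >= 0 & tt < length(tr$rate)
      idx <- tt[keep] + 1L
    }
    if (!any(keep)) next
    acc[keep] <- acc[keep] + tr$rate[idx]
    cnt[keep] <- cnt[keep] + 1L
  }
  if (all(cnt == 0)) stop("window contains no trial data")
  m <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  list(mean = m, n = cnt)
}

# trial-averaged eye velocity, motion aligned; 2 x T
.trial_average_eye <- function(trials, window_ms) {
  nt <- window_ms[2] - window_ms[1] + 1
  acc <- matrix(0, 2, nt)
  cnt <- integer(nt)
  for (tr in trials) {
    tt <- tr$motion_onset + (window_ms[1]:window_ms[2])
    keep <- tt >= 0 & tt < ncol(tr$eye)
    if (!any(keep)) next
    acc[, keep] <- acc[, keep] + tr$eye[, tt[keep] + 1L]
    cnt[keep] <- cnt[keep] + 1L
  }
  if (all(cnt == 0)) stop("window contains no eye data")
  sweep(acc, 2, pmax(cnt, 1L), "/")
}

#' Gaussian smoothing with edge renormalization
#'
#' Convolution with a unit-mass Gaussian kernel truncated at +/- 4 sigma; near
#' the edges the kernel is renormalized over its valid support so that a
#' constant trace passes through unchanged and the output has the input's
#' length.
#'
#' @param trace numeric vector (1-ms samples). `NA`s are treated as missing
#'   support (renormalized around).
#' @param sigma_ms kernel standard deviation in ms.
#' @return smoothed trace, same length.
#' @export
.smooth_cache <- new.env(parent = emptyenv())

# smoothing matrix: out = S %*% x; row i holds the truncated, edge-
# renormalized Gaussian centered on sample i
.smooth_matrix <- function(n, sigma_ms) {
  key <- paste0(n, "_", sigma_ms)
  S <- .smooth_cache[[key]]
  if (!is.null(S)) return(S)
  half <- max(1L, ceiling(4 * sigma_ms))
  k <- stats::dnorm(seq(-half, half), sd = sigma_ms)
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    w <- k[j - i + half + 1L]
    S[i, j] <- w / sum(w)
  }
  .smooth_cache[[key]] <- S
  S
}

gaussian_smooth <- function(trace, sigma_ms) {
  n <- length(trace)
  if (n < 1) stop("empty trace")
  if (!is.finite(sigma_ms) || sigma_ms <= 0) stop("sigma_ms must be > 0")
  if (!anyNA(trace)) {
    return(as.vector(.smooth_matrix(n, sigma_ms) %*% trace))
  }
  # missing-support path: renormalize the kernel over finite samples
  half <- max(1L, ceiling(4 * sigma_ms))
  k <- stats::dnorm(seq(-half, half), sd = sigma_ms)
  k <- k / sum(k)
  ok <- as.numeric(is.finite(trace))
  x <- ifelse(is.finite(trace), trace, 0)
  num <- stats::convolve(x, rev(k), type = "open")[half + seq_len(n)]
  den <- stats::convolve(ok, rev(k), type = "open")[half + seq_len(n)]
  ifelse(den > 1e-12, num / den, NA_real_)
}

# row-wise smoothing of a matrix along time (columns)
.smooth_rows <- function(M, sigma_ms) {
  M %*% t(.smooth_matrix(ncol(M), sigma_ms))
}

#' Preferred direction as a weighted circular mean
#'
#' The mean parameter of a von Mises fit to direction tuning: the circular
#' mean of the eight direction labels weighted by nonnegative responses.
#'
#' @param weights nonnegative responses, one per direction.
#' @param directions direction labels in degrees (default the 45-degree grid).
#' @return list with `direction` (deg in `[0,360)`, `NA` when undefined),
#'   `resultant` (mean resultant length in `[0,1]`), and `defined`.
#' @export
preferred_direction <- function(weights, directions = DIR_GRID) {
  if (length(weights) != length(directions)) {
    stop("weights and directions must have equal length")
  }
  if (any(weights < 0)) stop("weights must be nonnegative (rectify first)")
  tot <- sum(weights)
  if (tot <= 0) {
    return(list(direction = NA_real_, resultant = 0, defined = FALSE))
  }
  rad <- directions * pi / 180
  s <- sum(weights * sin(rad)) / tot
  c <- sum(weights * cos(rad)) / tot
  r <- sqrt(s^2 + c^2)
  if (r < 1e-9) {
    return(list(direction = NA_real_, resultant = r, defined = FALSE))
  }
  list(direction = wrap360(atan2(s, c) * 180 / pi), resultant = r,
       defined = TRUE)
}

#' Rotate direction-keyed tuning into block-relative coordinates
#'
#' Re-keys a response at absolute direction d to relative direction
#' (d - block_direction) mod 360, so that the single-direction block's
#' direction becomes 0 degrees.
#'
#' @param tuning_by_direction named vector or list keyed by absolute direction
#'   (degrees on the 45-degree grid).
#' @param block_direction the single-direction block's direction (on-grid).
#' @return object of the same type re-keyed by relative direction.
#' @export
rotate_directions <- function(tuning_by_direction, block_direction) {
  dirs <- as.numeric(names(tuning_by_direction))
  if (any(is.na(dirs))) stop("tuning must be keyed by numeric directions")
  check_on_grid(dirs, "tuning directions")
  check_on_grid(block_direction, "block_direction")
  rel <- wrap360(dirs - block_direction)
  out <- tuning_by_direction
  names(out) <- rel
  out[order(rel)]
}

#' Rotate eye velocity into block-relative coordinates
#'
#' Applies the same rotation used for tuning curves to the horizontal and
#' vertical velocity components, so speed is preserved at every sample.
#'
#' @param eye 2 x T velocity matrix (rows horizontal, vertical).
#' @param block_direction rotation in degrees (the block direction maps to 0).
#' @return rotated 2 x T matrix.
#' @export
rotate_eye_velocity <- function(eye, block_direction) {
  th <- -block_direction * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  R %*% eye
}

#' Preparatory firing-rate modulation
#'
#' Mean rate over the last 100 ms of fixation minus the mean rate 151-250 ms
#' after fixation onset. Positive values classify a sample as an increase
#' cell, negative as a decrease cell.
#'
#' @param rate_trace rate trace aligned at fixation onset (sample 1 = 0 ms).
#' @param events list with `motion_onset` (ms after fixation onset).
#' @param early_window early-fixation reference window in ms (default
#'   `c(151, 250)`; the single-trial variant of the analysis uses
#'   `c(150, 250)`).
#' @return scalar modulation in spikes/s.
#' @export
prep_modulation <- function(rate_trace, events, early_window = c(151, 250)) {
  tf <- events$motion_onset
  if (is.null(tf) || tf < 350) stop("fixation must last at least 350 ms")
  if (tf > length(rate_trace)) stop("windows extend outside the trace")
  late <- (tf - 100):(tf - 1) + 1L
  early <- early_window[1]:early_window[2] + 1L
  mean(rate_trace[late]) - mean(rate_trace[early])
}

#' Pursuit-related firing-rate modulation
#'
#' Mean rate 51-150 ms after motion onset minus the mean rate over the last
#' 100 ms of fixation.
#'
#' @inheritParams prep_modulation
#' @return scalar modulation in spikes/s.
#' @export
purs_modulation <- function(rate_trace, events) {
  tf <- events$motion_onset
  if (is.null(tf) || tf < 100) stop("fixation too short")
  if (tf + 150 > length(rate_trace) - 1) stop("windows extend outside the trace")
  late <- (tf + 51):(tf + 150) + 1L
  fix <- (tf - 100):(tf - 1) + 1L
  mean(rate_trace[late]) - mean(rate_trace[fix])
}

#' Classify a unit's block-relative direction
#'
#' Same direction: absolute circular difference < 45 deg; orthogonal:
#' in [45, 135); opposite: >= 135.
#'
#' @param pref_direction preferred direction (deg); `NA` gives `"unclassified"`.
#' @param block_direction block direction (deg).
#' @return one of `"same"`, `"orthogonal"`, `"opposite"`, `"unclassified"`.
#' @export
classify_direction_group <- function(pref_direction, block_direction) {
  if (is.na(pref_direction) || is.na(block_direction)) return("unclassified")
  d <- circ_diff(pref_direction, block_direction)
  if (d < 45) "same" else if (d < 135) "orthogonal" else "opposite"
}

#' Assemble the pseudo-population matrices
#'
#' Builds, from per-unit recording sessions, the rotated, smoothed,
#' trial-averaged population matrices used by every downstream analysis: the
#' 8-direction rate-modulation matrix `N_8D` (rows mean-centered across all
#' 2000 columns and normalized to unit range), the matched 2 x 2000 eye
#' velocity matrix `E` (shifted forward by `lag_ms`), the fixation matrix
#' `N_1D` (first 150 ms and last 50 ms discarded, zeroed at the first
#' retained sample, scaled by the 8-direction ranges), the raw preparatory
#' and pursuit matrices `N_prep` / `N_purs` for PCA, cross-validation
#' matrices for the single-direction block, and per-row metadata (preferred
#' direction, relative-direction bin, normalization range, per-trial
#' preparatory modulations).
#'
#' Each (unit, single-direction block) pair contributes one row; rows with an
#' 8-direction range below `1e-6` times the population median range are
#' excluded and reported.
#'
#' @param sessions list of `recording_session` objects (see
#'   [generate_population()] / [read_dataset()]).
#' @param sigma_ms Gaussian smoothing sd in ms (default 20).
#' @param lag_ms behavioral lag: eye velocity is taken `lag_ms` after the
#'   rates (default 25).
#' @param purs_window_ms window after motion onset for the pursuit PCA matrix
#'   (125 ms per condition; default `c(0, 124)`).
#' @return object of class `pseudopopulation`.
#' @export
build_pseudopopulation <- function(sessions, sigma_ms = 20, lag_ms = 25,
                                   purs_window_ms = c(0, 124)) {
  units <- split(sessions, vapply(sessions, function(s) s$unit_id, character(1)))
  fix_len <- 1600L
  n8_win <- c(0L, 249L)
  rows <- list()
  e_acc <- matrix(0, 2, 8 * 250); e_n <- 0L
  ecv_acc <- NULL; ecv_n <- 0L
  for (uid in names(units)) {
    us <- units[[uid]]
    types <- vapply(us, function(s) s$block_type, character(1))
    s8 <- us[types == "eight_direction"]
    s1s <- us[types == "single_direction"]
    if (length(s8) == 0 || length(s1s) == 0) {
      stop(sprintf("unit %s lacks an 8-direction or a single-direction block", uid))
    }
    s8 <- s8[[1]]
    has_eye <- !is.null(s8$trials[[1]]$eye)
    # 8-direction block: per-direction smoothed averages and eye velocity
    dirs8 <- vapply(s8$trials, function(tr) tr$direction, numeric(1))
    rate_by_dir <- list(); eye_by_dir <- list(); tuning_w <- numeric(8)
    for (k in seq_along(DIR_GRID)) {
      d <- DIR_GRID[k]
      trs <- s8$trials[dirs8 == d]
      if (length(trs) == 0) stop(sprintf("unit %s: no trials at %d deg", uid, d))
      ta <- trial_average(trs, "motion", n8_win)
      rate_by_dir[[as.character(d)]] <- gaussian_smooth(ta$mean, sigma_ms)
      if (has_eye) eye_by_dir[[as.character(d)]] <-
        .trial_average_eye(trs, n8_win + lag_ms)
      # pursuit-epoch response for preferred-direction estimation
      fx <- mean(vapply(trs, function(tr) {
        tf <- tr$motion_onset
        mean(tr$rate[(tf - 100):(tf - 1) + 1L])
      }, numeric(1)))
      resp <- mean(vapply(trs, function(tr) {
        tf <- tr$motion_onset
        mean(tr$rate[(tf + 51):(tf + 150) + 1L])
      }, numeric(1)))
      tuning_w[k] <- max(0, resp - fx)  # rectified, baseline-subtracted
    }
    pd <- preferred_direction(tuning_w)
    for (s1 in s1s) {
      bd <- s1$block_direction
      rot_rate <- rotate_directions(rate_by_dir, bd)
      r8 <- unlist(rot_rate, use.names = FALSE)  # 2000, relative order 0..315
      if (has_eye) {
        rot_eye <- rotate_directions(eye_by_dir, bd)
        e8 <- do.call(cbind, lapply(rot_eye, rotate_eye_velocity,
                                    block_direction = bd))
      }
      # fixation average (ragged), trimmed and anchored; samples beyond the
      # longest fixation in this block hold the last observed average
      ta1 <- trial_average(s1$trials, "fixation", c(0L, fix_len - 1L))
      sm1 <- gaussian_smooth(ta1$mean, sigma_ms)
      if (anyNA(sm1)) {
        last <- max(which(is.finite(sm1)))
        if (last < length(sm1)) sm1[(last + 1L):length(sm1)] <- sm1[last]
      }
      n1 <- sm1[(150:1549) + 1L]
      # pursuit matrix: one 125-ms segment per speed x contrast condition
      conds <- unique(data.frame(
        speed = vapply(s1$trials, function(tr) tr$speed, numeric(1)),
        contrast = vapply(s1$trials, function(tr) tr$contrast, numeric(1))))
      conds <- conds[order(conds$speed, conds$contrast), , drop = FALSE]
      purs_segs <- list(); eye_segs <- list()
      for (ci in seq_len(nrow(conds))) {
        sel <- vapply(s1$trials, function(tr) {
          tr$speed == conds$speed[ci] && tr$contrast == conds$contrast[ci]
        }, logical(1))
        ta <- trial_average(s1$trials[sel], "motion", purs_window_ms)
        purs_segs[[ci]] <- gaussian_smooth(ta$mean, sigma_ms)
        if (has_eye) eye_segs[[ci]] <- rotate_eye_velocity(
          .trial_average_eye(s1$trials[sel], purs_window_ms + lag_ms), bd)
      }
      # per-trial preparatory modulation for the single-trial bootstrap
      tprep <- data.frame(
        duration = vapply(s1$trials, function(tr) tr$motion_onset, numeric(1)),
        modulation = vapply(s1$trials, function(tr) {
          prep_modulation(tr$rate, list(motion_onset = tr$motion_onset),
                          early_window = c(150, 250))
        }, numeric(1)))
      rows[[length(rows) + 1L]] <- list(
        unit_id = uid, block_id = s1$block_id %||% NA_character_,
        block_direction = bd, r8 = r8, n1 = n1,
        purs = unlist(purs_segs, use.names = FALSE),
        purs_conds = conds,
        pref = pd, trial_prep = tprep,
        prep_mod = mean(vapply(s1$trials, function(tr) {
          prep_modulation(tr$rate, list(motion_onset = tr$motion_onset))
        }, numeric(1))),
        purs_mod = mean(vapply(s1$trials, function(tr) {
          purs_modulation(tr$rate, list(motion_onset = tr$motion_onset))
        }, numeric(1))))
      if (has_eye) {
        e_acc <- e_acc + e8; e_n <- e_n + 1L
        ecv <- do.call(cbind, eye_segs)
        if (is.null(ecv_acc)) ecv_acc <- ecv * 0
        ecv_acc <- ecv_acc + ecv; ecv_n <- ecv_n + 1L
      }
    }
  }
  nr <- length(rows)
  N8 <- t(vapply(rows, function(r) r$r8, numeric(2000)))
  rng <- apply(N8, 1, function(v) diff(range(v)))
  med <- stats::median(rng)
  keep <- rng >= 1e-6 * med
  excluded <- which(!keep)
  ctr <- rowMeans(N8)
  N8n <- (N8 - ctr) / rng
  N1 <- t(vapply(rows, function(r) r$n1, numeric(1400)))
  N1n <- (N1 - N1[, 1]) / rng
  plens <- vapply(rows, function(r) length(r$purs), integer(1))
  if (length(unique(plens)) != 1) {
    stop("single-direction blocks present different condition sets; ",
         "pursuit matrices cannot be aligned across rows")
  }
  Np <- t(vapply(rows, function(r) r$purs, numeric(plens[1])))
  Npcv <- (Np - ctr) / rng  # pursuit rates on the 8-direction scale, for CV
  meta <- data.frame(
    unit_id = vapply(rows, function(r) r$unit_id, character(1)),
    block_id = vapply(rows, function(r) as.character(r$block_id), character(1)),
    block_direction = vapply(rows, function(r) r$block_direction, numeric(1)),
    pref_direction = vapply(rows, function(r) r$pref$direction %||% NA_real_,
                            numeric(1)),
    resultant = vapply(rows, function(r) r$pref$resultant, numeric(1)),
    range = rng, center = ctr, excluded = !keep,
    prep_mod = vapply(rows, function(r) r$prep_mod, numeric(1)),
    purs_mod = vapply(rows, function(r) r$purs_mod, numeric(1)),
    stringsAsFactors = FALSE)
  meta$rel_bin <- wrap360(round(
    wrap360(meta$pref_direction - meta$block_direction) / 45) * 45)
  meta$direction_group <- mapply(classify_direction_group,
                                 meta$pref_direction, meta$block_direction)
  trial_prep <- lapply(rows, function(r) r$trial_prep)
  sel <- which(keep)
  structure(list(
    N_8D = N8n[sel, , drop = FALSE],
    E = if (e_n > 0) e_acc / e_n else NULL,
    N_1D = N1n[sel, , drop = FALSE],
    N_prep = N1[sel, , drop = FALSE],
    N_purs = Np[sel, , drop = FALSE],
    N_purs_cv = Npcv[sel, , drop = FALSE],
    E_purs = if (!is.null(ecv_acc)) ecv_acc / max(ecv_n, 1L) else NULL,
    purs_conds = rows[[1]]$purs_conds,
    meta = meta[sel, , drop = FALSE],
    trial_prep = trial_prep[sel],
    excluded = meta[excluded, , drop = FALSE],
    params = list(sigma_ms = sigma_ms, lag_ms = lag_ms,
                  n8_window_ms = n8_win, purs_window_ms = purs_window_ms)),
    class = "pseudopopulation")
}

#' @export
print.pseudopopulation <- function(x, ...) {
  cat(sprintf(
    "pseudopopulation: %d rows (%d excluded); N_8D %d x %d, N_1D %d x %d, N_purs %d x %d\n",
    nrow(x$N_8D), nrow(x$excluded), nrow(x$N_8D), ncol(x$N_8D),
    nrow(x$N_1D), ncol(x$N_1D), nrow(x$N_purs), ncol(x$N_purs)))
  invisible(x)
}
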