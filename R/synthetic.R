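# Synthetic populations and behavior with planted ground truth.
#
# The generator emulates the experimental design of the recordings the
# pipeline analyzes: interleaved 8-direction pursuit blocks at 15 deg/s,
# single-direction blocks with speed/contrast conditions, fixation durations
# uniform on 800-1600 ms, two neuron subpopulations with von Mises direction
# tuning and linear preparatory ramps, a planted linear readout that generates
# eye velocity from the processed population rate (delayed 25 ms), and
# pulse-probe behavioral sessions whose response amplitudes follow a planted
# time- and direction-dependent gain. Every planted parameter is returned in
# a `planted_truth` object so downstream estimators can be checked by
# parameter recovery.

#' Configuration for the synthetic-data generator
#'
#' Defaults are the study conditions the generator emulates; they are chosen
#' once and are not analysis knobs.
#'
#' @param n_neurons number of units (>= 16; a multiple of 64 balances the
#'   8 preferred directions x 8 relative-direction bins exactly).
#' @param frac_subpop2 fraction of units in subpopulation 2 (preparatory
#'   tuning rectified away from the preferred direction).
#' @param kappa von Mises concentration of pursuit direction tuning.
#' @param pursuit_amp,prep_amp_1,prep_amp_2,baseline rate parameters, spikes/s.
#' @param subpop2_offset additive preparatory offset c for subpopulation 2
#'   (spikes/s): its ramp amplitude is
#'   `prep_amp_2 * max(0, -cos(delta)) + c`.
#' @param noise_sd sd of additive Gaussian rate noise per 1-ms bin, spikes/s;
#'   eye-velocity noise is `eye_noise_scale * noise_sd` deg/s so that
#'   `noise_sd = 0` makes the whole dataset deterministic.
#' @param eye_noise_scale see `noise_sd`.
#' @param trials_per_condition trials per speed x contrast condition
#'   (single-direction block).
#' @param trials_8dir trials per direction in the 8-direction block
#'   (default: `trials_per_condition`).
#' @param include_eye generate per-trial eye-velocity traces (`TRUE`); with
#'   `FALSE` only firing rates are generated, which is enough for the
#'   subspace analyses and much faster.
#' @param fixation_range fixation-duration range in ms (uniform draw).
#' @param block_specs optional data frame with columns `direction`, `speed`,
#'   `contrast`, `context` describing the single-direction blocks to cycle
#'   across units; directions must lie on the 45-degree grid. `NULL` uses a
#'   balanced design (each relative-direction bin equally represented, one
#'   mixed-context block per unit covering 2/10/20 deg/s at 12 and 100
#'   percent contrast). Context `mixed` presents all speeds equally;
#'   `fast`/`slow` present 80/20 blends of 20/10 and 2/10 deg/s;
#'   `control` presents 10 deg/s only.
#' @param paired_blocks give every unit a second single-direction block 180
#'   degrees from its first (toward/away pairs for demixed PCA).
#' @param readout_scale deg/s per normalized rate unit for the planted
#'   readout columns `readout_scale * (cos, sin)(pref)/n_rows`.
#' @param gain_params named vector `(g0, a_dir, b0, b1)` of the planted gain
#'   `G(t, delta) = g0 + a_dir cos(delta) + (b0 + b1 cos(delta)) t` (t in s).
#' @param context_factors multiplicative gain factors for fast/slow/control
#'   speed contexts.
#' @param theta_target optional planted preparatory-vs-pursuit loading angle
#'   in degrees (0-180); overrides the subpopulation preparatory rule with a
#'   sign-flipped direction-independent ramp pattern realizing the angle.
#' @param n_sessions,trials_per_session pulse-probe experiment size.
#' @param session_gain_sd,context_gain_sd relative sd of session-level and
#'   context-block-level multiplicative gain variability (emulating
#'   session-to-session scatter of visuomotor gain); both are inactive when
#'   `noise_sd = 0` so noise-free datasets stay fully deterministic.
#' @param saccade_rate fraction of pulse trials carrying an inserted saccade
#'   transient (for rejection testing); `saccade_amp` deg/s, `saccade_dur` ms.
#' @param seed integer master seed; identical seeds give bit-identical
#'   datasets.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_neurons = 240,
                             frac_subpop2 = 0.3,
                             kappa = 2,
                             pursuit_amp = 40,
                             prep_amp_1 = 15,
                             prep_amp_2 = 8,
                             subpop2_offset = 2,
                             baseline = 45,
                             noise_sd = 2,
                             eye_noise_scale = 0.1,
                             trials_per_condition = 4,
                             trials_8dir = NULL,
                             include_eye = TRUE,
                             fixation_range = c(800, 1600),
                             block_specs = NULL,
                             paired_blocks = FALSE,
                             readout_scale = 50,
                             gain_params = c(g0 = 0.3, a_dir = 0.09,
                                             b0 = 0.145, b1 = 0.065),
                             context_factors = c(fast = 1.025, slow = 0.77,
                                                 control = 1),
                             theta_target = NULL,
                             n_sessions = 30,
                             trials_per_session = 160,
                             session_gain_sd = 0.12,
                             context_gain_sd = 0.17,
                             saccade_rate = 0.1,
                             saccade_amp = 200,
                             saccade_dur = 30,
                             seed = 1) {
  cfg <- list(n_neurons = n_neurons, frac_subpop2 = frac_subpop2,
              kappa = kappa, pursuit_amp = pursuit_amp,
              prep_amp_1 = prep_amp_1, prep_amp_2 = prep_amp_2,
              subpop2_offset = subpop2_offset, baseline = baseline,
              noise_sd = noise_sd, eye_noise_scale = eye_noise_scale,
              trials_per_condition = trials_per_condition,
              trials_8dir = trials_8dir %||% trials_per_condition,
              include_eye = include_eye,
              fixation_range = fixation_range, block_specs = block_specs,
              paired_blocks = paired_blocks, readout_scale = readout_scale,
              gain_params = gain_params, context_factors = context_factors,
              theta_target = theta_target, n_sessions = n_sessions,
              trials_per_session = trials_per_session,
              session_gain_sd = session_gain_sd,
              context_gain_sd = context_gain_sd,
              saccade_rate = saccade_rate, saccade_amp = saccade_amp,
              saccade_dur = saccade_dur, seed = seed)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_neurons < 16) stop("n_neurons must be >= 16")
  if (cfg$frac_subpop2 < 0 || cfg$frac_subpop2 > 1) {
    stop("frac_subpop2 must be in [0, 1]")
  }
  if (cfg$fixation_range[1] < 400 || diff(cfg$fixation_range) < 0) {
    stop("invalid fixation_range")
  }
  if (!is.null(cfg$block_specs)) {
    bs <- cfg$block_specs
    if (!is.data.frame(bs) || !all(c("direction", "speed", "contrast",
                                     "context") %in% names(bs))) {
      stop("block_specs must have columns direction, speed, contrast, context")
    }
    if (any(wrap360(bs$direction) %% 45 != 0)) {
      stop("block_specs direction must be a multiple of 45 degrees")
    }
    bad <- setdiff(unique(as.character(bs$context)),
                   c("mixed", "control", "fast", "slow"))
    if (length(bad) > 0) {
      stop(sprintf("unknown block context '%s'", bad[1]))
    }
  }
  if (!is.null(cfg$theta_target) &&
      (cfg$theta_target < 0 || cfg$theta_target > 180)) {
    stop("theta_target must be in [0, 180] degrees")
  }
  gp <- cfg$gain_params
  if (length(gp) != 4) stop("gain_params must have 4 elements (g0,a_dir,b0,b1)")
  invisible(cfg)
}

# von Mises tuning centered at 0, normalized to peak 1 and zero mean over the
# 8-direction grid; negative away from the preferred direction.
.dir_tuning <- function(delta_deg, kappa) {
  e <- exp(kappa * cos(delta_deg * pi / 180))
  m <- mean(exp(kappa * cos(DIR_GRID * pi / 180)))
  (e - m) / (exp(kappa) - m)
}

# pursuit temporal profile: 0 before latency, linear rise to a sustained
# plateau, plus an optional latency-locked transient (units differ in their
# blend of transient and sustained dynamics, as real pursuit neurons do)
.purs_profile <- function(tau_ms, latency_ms, rise_ms = 80,
                          trans_amp = 0, trans_center = 120,
                          trans_width = 40) {
  p <- pmin(pmax((tau_ms - latency_ms) / rise_ms, 0), 1)
  if (trans_amp != 0) {
    p <- p + trans_amp *
      exp(-((tau_ms - latency_ms - trans_center)^2) / (2 * trans_width^2)) *
      (tau_ms >= latency_ms)
  }
  p
}

.contrast_latency <- function(contrast) ifelse(contrast >= 50, 60, 90)

# preparatory ramp value at time t ms after fixation onset (amplitude 1
# reached at 1400 ms; starts rising at 150 ms)
.ramp_val <- function(t_ms) pmax(0, (t_ms - 150) / 1250)

# evenly interspersed boolean pattern with given fraction (Bresenham)
.spread_flags <- function(n, frac) {
  diff(c(0, floor(cumsum(rep(frac, n)) + 1e-9))) >= 1
}

# speed x contrast condition table for a single-direction block, with trial
# counts realizing the context's blend of target speeds: fast is 80% at
# 20 deg/s and 20% at 10; slow is 80% at 2 and 20% at 10; control is 100%
# at 10; "mixed" is the design simplification that covers all three speeds
# equally so one block supports the full speed/contrast cross-validation
.context_conds <- function(context, t) {
  sp <- switch(context,
    mixed = data.frame(speed = c(2, 10, 20), n = c(t, t, t)),
    control = data.frame(speed = 10, n = 2 * t),
    fast = data.frame(speed = c(20, 10), n = c(4 * t, t)),
    slow = data.frame(speed = c(2, 10), n = c(4 * t, t)),
    stop(sprintf("unknown block context '%s'", context)))
  out <- merge(sp, data.frame(contrast = c(12, 100)))
  out[order(out$speed, out$contrast), c("speed", "contrast", "n")]
}

#' Generate a synthetic neural population with planted ground truth
#'
#' Each unit receives one 8-direction block (15 deg/s, high contrast) and one
#' or two single-direction blocks (2/10/20 deg/s x 12/100 percent contrast).
#' Pursuit responses follow zero-mean von Mises direction tuning with
#' contrast-dependent latency; preparatory ramps rise linearly from 150 ms
#' after fixation onset with subpopulation-specific direction tuning; eye
#' velocity in the pursuit epoch is the planted readout `W_true` applied to
#' the smoothed, mean-centered, range-normalized population rate delayed
#' 25 ms, so that with `noise_sd = 0` every downstream estimator recovers its
#' planted parameter exactly.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_dataset`: list with `sessions` (list of
#'   `recording_session`), `truth` (class `planted_truth`), and `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_neurons
  # relative direction cycles fastest so the eight relative-direction bins
  # are balanced for any multiple of 8 units
  rel <- DIR_GRID[((seq_len(n) - 1L) %% 8L) + 1L]
  pref <- DIR_GRID[(((seq_len(n) - 1L) %/% 8L) %% 8L) + 1L]
  subpop <- ifelse(.spread_flags(n, config$frac_subpop2), 2L, 1L)
  # fixed per-unit response heterogeneity (tuning width, latency, rise time);
  # drawn once from the seed, these make the population rate matrix full row
  # rank, as real response-timing diversity does
  kappa_u <- config$kappa * stats::runif(n, 0.75, 1.25)
  lat_u <- stats::runif(n, -15, 15)      # added to the contrast latency, ms
  rise_u <- stats::runif(n, 50, 120)     # rise time, ms
  tamp_u <- stats::runif(n, 0, 0.4)      # transient amplitude (rel. sustained)
  tcen_u <- stats::runif(n, 60, 200)     # transient center after latency, ms
  twid_u <- stats::runif(n, 20, 60)      # transient width, ms

  # single-direction block specs per unit
  if (is.null(config$block_specs)) {
    bd1 <- wrap360(pref - rel)
    specs <- lapply(seq_len(n), function(i) {
      out <- list(list(direction = bd1[i], context = "mixed"))
      if (config$paired_blocks) {
        out <- c(out, list(list(direction = wrap360(bd1[i] + 180),
                                context = "mixed")))
      }
      out
    })
  } else {
    bs <- config$block_specs
    specs <- lapply(seq_len(n), function(i) {
      j <- ((i - 1L) %% nrow(bs)) + 1L
      list(list(direction = wrap360(bs$direction[j]),
                context = as.character(bs$context[j])))
    })
  }

  # rows: one per (unit, single-direction block)
  row_unit <- integer(0); row_bd <- numeric(0); row_block <- integer(0)
  for (i in seq_len(n)) {
    for (b in seq_along(specs[[i]])) {
      row_unit <- c(row_unit, i)
      row_bd <- c(row_bd, specs[[i]][[b]]$direction)
      row_block <- c(row_block, b)
    }
  }
  nr <- length(row_unit)
  row_rel <- wrap360(pref[row_unit] - row_bd)

  # planted per-row amplitudes
  purs_amp <- config$pursuit_amp * .dir_tuning(row_rel, kappa_u[row_unit])
  if (is.null(config$theta_target)) {
    prep_amp <- ifelse(
      subpop[row_unit] == 1L,
      config$prep_amp_1 * cos(row_rel * pi / 180),
      config$prep_amp_2 * pmax(0, -cos(row_rel * pi / 180)) +
        config$subpop2_offset)
  } else {
    # plant the sign-flip fraction stratified across relative-direction bins
    # (largest-remainder allocation of the global flip count), so the
    # planted angle is a population-geometry property, not confounded with
    # direction, and survives small fractions
    f <- (1 - cos(config$theta_target * pi / 180)) / 2
    total <- round(f * nr)
    bins_rows <- lapply(DIR_GRID, function(b) which(row_rel == b))
    quota <- f * lengths(bins_rows)
    cnt <- floor(quota)
    extra <- total - sum(cnt)
    if (extra > 0) {
      give <- order(quota - cnt, decreasing = TRUE)[seq_len(extra)]
      cnt[give] <- cnt[give] + 1L
    } else if (extra < 0) {
      take <- order(quota - cnt)[seq_len(-extra)]
      cnt[take] <- pmax(0L, cnt[take] - 1L)
    }
    flip <- logical(nr)
    for (k in seq_along(bins_rows)) {
      nb <- length(bins_rows[[k]])
      if (cnt[k] > 0 && nb > 0) {
        pos <- unique(ceiling((seq_len(min(cnt[k], nb)) - 0.5) * nb /
                                min(cnt[k], nb)))
        flip[bins_rows[[k]][pos]] <- TRUE
      }
    }
    prep_amp <- config$prep_amp_1 * sign(purs_amp) * ifelse(flip, -1, 1)
  }

  # deterministic smoothed 8-direction rates per unit (8 x 250 each),
  # assembled into the row-wise rotated, normalized N_8D to define E
  unit_profile <- function(i, tau_ms, contrast) {
    .purs_profile(tau_ms, .contrast_latency(contrast) + lat_u[i], rise_u[i],
                  tamp_u[i], tcen_u[i], twid_u[i])
  }
  prof8 <- lapply(seq_len(n), function(i) unit_profile(i, 0:249, 100))
  det8 <- lapply(seq_len(n), function(i) {
    amp <- config$pursuit_amp * .dir_tuning(DIR_GRID - pref[i], kappa_u[i])
    m <- outer(amp, prof8[[i]]) + config$baseline  # 8 x 250, absolute dirs
    .smooth_rows(m, 20)
  })
  N8 <- matrix(0, nr, 2000)
  for (r in seq_len(nr)) {
    ord <- match(wrap360(DIR_GRID + row_bd[r]), DIR_GRID)  # abs dir per rel slot
    N8[r, ] <- as.vector(t(det8[[row_unit[r]]][ord, ]))
  }
  ctr <- rowMeans(N8)
  rng <- apply(N8, 1, function(v) diff(range(v)))
  N8n <- (N8 - ctr) / rng

  # readout columns follow the cosine rule on the unit's block-relative
  # preferred direction (the frame the pseudo-population is assembled in)
  W <- rbind(config$readout_scale * cos(row_rel * pi / 180) / nr,
             config$readout_scale * sin(row_rel * pi / 180) / nr)
  E_rel <- W %*% N8n  # 2 x 2000, block-relative coordinates

  # single-direction pursuit conditions and their relative-frame eye
  # velocity, for every speed x contrast combination any context can present
  all_conds <- expand.grid(speed = c(2, 10, 20), contrast = c(12, 100))
  purs_win <- 0:124
  pcv <- lapply(seq_len(nrow(all_conds)), function(ci) {
    M <- t(vapply(seq_len(nr), function(r) {
      purs_amp[r] * all_conds$speed[ci] / 15 *
        unit_profile(row_unit[r], purs_win, all_conds$contrast[ci]) +
        config$baseline
    }, numeric(length(purs_win))))
    Ms <- .smooth_rows(M, 20)
    Mn <- (Ms - ctr) / rng
    list(det = M, E = W %*% Mn)
  })
  names(pcv) <- paste(all_conds$speed, all_conds$contrast, sep = "_")
  E_prep_dir <- W %*% (prep_amp / rng)  # eye term per unit ramp value

  sessions <- list()
  sd_eye <- config$eye_noise_scale * config$noise_sd
  for (i in seq_len(n)) {
    # 8-direction block
    trials <- list()
    for (d in DIR_GRID) {
      purs_seg8 <- config$baseline +
        config$pursuit_amp * .dir_tuning(d - pref[i], kappa_u[i]) * prof8[[i]]
      bd <- row_bd[row_unit == i][1]
      reld <- wrap360(d - bd)
      seg <- E_rel[, (match(reld, DIR_GRID) - 1L) * 250L + (1:250)]
      th <- bd * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      Rseg <- R %*% seg
      for (k in seq_len(config$trials_8dir)) {
        tf <- floor(stats::runif(1, config$fixation_range[1],
                                 config$fixation_range[2] + 1))
        len <- tf + 301L
        rate <- rep(config$baseline, len)
        rate[tf + (0:249) + 1L] <- purs_seg8
        rate[(tf + 250 + 1L):len] <- rate[tf + 250]
        if (config$noise_sd > 0) {
          rate <- rate + stats::rnorm(len, 0, config$noise_sd)
        }
        eye <- NULL
        if (config$include_eye) {
          # eye from the planted readout, shared behavior expressed in this
          # unit's first block-direction frame
          eye <- matrix(0, 2, len)
          fill <- tf + 25 + (0:249) + 1L
          eye[, fill] <- Rseg
          eye[, (tf + 275 + 1L):len] <- eye[, tf + 275]
          if (sd_eye > 0) {
            eye[, fill] <- eye[, fill] +
              matrix(stats::rnorm(2 * length(fill), 0, sd_eye), 2)
          }
        }
        trials[[length(trials) + 1L]] <- list(
          direction = d, speed = 15, contrast = 100, motion_onset = tf,
          rate = rate, eye = eye)
      }
    }
    sessions[[length(sessions) + 1L]] <- structure(list(
      unit_id = sprintf("u%03d", i), block_id = "8dir",
      block_type = "eight_direction", block_direction = NA_real_,
      context = "control", trials = trials), class = "recording_session")

    # single-direction blocks
    for (b in seq_along(specs[[i]])) {
      r <- which(row_unit == i & row_block == b)
      bd <- row_bd[r]
      th <- bd * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      conds <- .context_conds(specs[[i]][[b]]$context,
                              config$trials_per_condition)
      trials <- list()
      for (ci in seq_len(nrow(conds))) {
        purs_seg <- purs_amp[r] * conds$speed[ci] / 15 *
          unit_profile(i, 0:300, conds$contrast[ci])
        cond_E <- pcv[[paste(conds$speed[ci], conds$contrast[ci],
                             sep = "_")]]$E
        for (k in seq_len(conds$n[ci])) {
          tf <- floor(stats::runif(1, config$fixation_range[1],
                                   config$fixation_range[2] + 1))
          len <- tf + 301L
          ramp <- .ramp_val(pmin(0:(len - 1L), tf))  # frozen at motion onset
          rate <- config$baseline + prep_amp[r] * ramp
          rate[tf + (0:300) + 1L] <- rate[tf + (0:300) + 1L] + purs_seg
          if (config$noise_sd > 0) {
            rate <- rate + stats::rnorm(len, 0, config$noise_sd)
          }
          eye <- NULL
          if (config$include_eye) {
            eye <- matrix(0, 2, len)
            seg <- cond_E + .ramp_val(tf) * as.vector(E_prep_dir)
            idx <- tf + 25 + purs_win + 1L
            eye[, idx] <- R %*% seg
            eye[, (max(idx) + 1L):len] <- eye[, max(idx)]
            if (sd_eye > 0) {
              eye[, idx] <- eye[, idx] +
                matrix(stats::rnorm(2 * length(idx), 0, sd_eye), 2)
            }
          }
          trials[[length(trials) + 1L]] <- list(
            direction = bd, speed = conds$speed[ci],
            contrast = conds$contrast[ci], motion_onset = tf,
            rate = rate, eye = eye)
        }
      }
      sessions[[length(sessions) + 1L]] <- structure(list(
        unit_id = sprintf("u%03d", i), block_id = sprintf("1dir%d", b),
        block_type = "single_direction", block_direction = bd,
        context = specs[[i]][[b]]$context, trials = trials),
        class = "recording_session")
    }
  }

  # planted loading sign patterns (the noise-free first principal components
  # after per-row range normalization) and the planted angle between them
  sp <- sign(prep_amp); sp[abs(prep_amp) < 1e-12] <- 0
  su <- sign(purs_amp); su[abs(purs_amp) < 1e-12] <- 0
  prep_load <- if (any(sp != 0)) sp / sqrt(sum(sp^2)) else sp
  purs_load <- if (any(su != 0)) su / sqrt(sum(su^2)) else su
  theta_true <- if (any(sp != 0) && any(su != 0)) {
    subspace_angle(prep_load, purs_load)
  } else NA_real_

  truth <- structure(list(
    W_true = W, theta_true = theta_true,
    prep_loadings = prep_load, purs_loadings = purs_load,
    subpop_labels = subpop[row_unit],
    gain_params = config$gain_params,
    preferred_directions = pref[row_unit],
    block_directions = row_bd, relative_directions = row_rel,
    prep_amplitudes = prep_amp, purs_amplitudes = purs_amp,
    normalization = list(center = ctr, range = rng),
    unit_index = row_unit,
    config = config), class = "planted_truth")

  structure(list(sessions = sessions, truth = truth, config = config),
            class = "synthetic_dataset")
}

#' Generate pulse-probe behavioral sessions with planted gain dynamics
#'
#' Half of the trials (on average) carry a 5 deg/s, 50 ms target-motion pulse
#' at a time drawn uniformly from 550-1350 ms after fixation onset (trials
#' whose 200 ms response window would cross motion onset are redrawn). The
#' peak eye-speed response equals
#' `5 * context_factor * G(t, delta)` with the planted gain
#' `G(t, delta) = g0 + a_dir cos(delta) + (b0 + b1 cos(delta)) t`; a raised-
#' cosine response transient peaks 100 ms after pulse onset. A fraction
#' `saccade_rate` of pulse trials receive an inserted saccade transient for
#' rejection testing.
#'
#' Two experiment types are generated: `"direction"` sessions (control
#' context, pulses in the four block-relative directions) and `"context"`
#' sessions (fast/slow pairs, same-direction pulses).
#'
#' @param config a [synthetic_config()].
#' @return object of class `behavioral_session_set`: list of sessions, each
#'   with fields `session_id`, `experiment`, `context`, `trials` (eye-speed
#'   trace over fixation, `pulse_onset`, `direction_class`, `has_pulse`,
#'   `has_saccade`, `motion_onset`).
#' @export
generate_pulse_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(child_seed(config$seed, 2L))
  gp <- config$gain_params
  G <- function(t_s, delta_deg) {
    gp[["g0"]] + gp[["a_dir"]] * cos(delta_deg * pi / 180) +
      (gp[["b0"]] + gp[["b1"]] * cos(delta_deg * pi / 180)) * t_s
  }
  bump <- function(len, onset, peak) {
    # raised cosine over onset+40 .. onset+160 ms, peak at onset+100
    y <- numeric(len)
    tt <- (onset + 40):(onset + 160)
    tt <- tt[tt < len]
    y[tt + 1L] <- peak * 0.5 * (1 - cos(2 * pi * (tt - onset - 40) / 120))
    y
  }
  sd_eye <- config$eye_noise_scale * config$noise_sd
  classes <- c(same = 0, orthogonal = 90, orthogonal = 270, opposite = 180)
  sessions <- list()
  # session-level and context-block-level gain scatter (off when noise off)
  vary <- config$noise_sd > 0
  make_trials <- function(ctxt, dirs, n_trials, session_mult = 1) {
    fac <- config$context_factors[[ctxt]] * session_mult *
      (if (vary) stats::rnorm(1, 1, config$context_gain_sd) else 1)
    trials <- list()
    for (k in seq_len(n_trials)) {
      has_pulse <- stats::runif(1) < 0.5
      repeat {
        tf <- floor(stats::runif(1, config$fixation_range[1],
                                 config$fixation_range[2] + 1))
        po <- if (has_pulse) floor(stats::runif(1, 550, 1351)) else NA
        if (!has_pulse || po + 200 < tf) break  # redraw if window crosses motion onset
      }
      speed <- numeric(tf)
      cls <- NA_character_; delta <- NA_real_
      if (has_pulse) {
        ci <- sample(length(dirs), 1)
        delta <- dirs[ci]; cls <- names(dirs)[ci]
        peak <- 5 * fac * G(po / 1000, delta)
        speed <- speed + bump(tf, po, peak)
      }
      has_sacc <- has_pulse && stats::runif(1) < config$saccade_rate
      if (has_sacc) {
        s0 <- po + floor(stats::runif(1, 0, 200 - config$saccade_dur))
        idx <- s0 + seq_len(config$saccade_dur)
        idx <- idx[idx <= tf]
        speed[idx] <- speed[idx] + config$saccade_amp
      }
      if (sd_eye > 0) speed <- speed + stats::rnorm(tf, 0, sd_eye)
      trials[[length(trials) + 1L]] <- list(
        speed = speed, pulse_onset = if (has_pulse) po else NA_real_,
        direction_class = cls, pulse_direction = delta, context = ctxt,
        has_pulse = has_pulse, has_saccade = has_sacc, motion_onset = tf)
    }
    trials
  }
  for (s in seq_len(config$n_sessions)) {
    sm <- if (vary) stats::rnorm(1, 1, config$session_gain_sd) else 1
    sessions[[length(sessions) + 1L]] <- list(
      session_id = sprintf("dir%02d", s), experiment = "direction",
      context = "control",
      trials = make_trials("control", classes, config$trials_per_session, sm))
  }
  n_ctx <- max(2L, floor(config$n_sessions * 26 / 30))
  for (s in seq_len(n_ctx)) {
    half <- config$trials_per_session %/% 2L
    sm <- if (vary) stats::rnorm(1, 1, config$session_gain_sd) else 1
    sessions[[length(sessions) + 1L]] <- list(
      session_id = sprintf("ctx%02d", s), experiment = "context",
      context = "paired",
      trials = c(make_trials("fast", classes[1], half, sm),
                 make_trials("slow", classes[1], half, sm)))
  }
  structure(list(sessions = sessions, gain_params = gp,
                 context_factors = config$context_factors,
                 config = config), class = "behavioral_session_set")
}

#' Planted ground truth of a synthetic dataset
#'
#' Returns the exact planted parameters (never estimates).
#'
#' @param dataset object produced by [generate_population()].
#' @return the `planted_truth` object.
#' @export
ground_truth <- function(dataset) {
  if (!inherits(dataset, "synthetic_dataset")) {
    stop("no planted truth available: not a dataset from generate_population()")
  }
  dataset$truth
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d sessions, %d rows, seed %d\n",
              length(x$sessions), length(x$truth$unit_index),
              x$config$seed))
  invisible(x)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf(
    "planted_truth: %d rows, theta_true = %.1f deg, %d/%d subpop-2 rows\n",
    length(x$unit_index), x$theta_true, sum(x$subpop_labels == 2),
    length(x$subpop_labels)))
  invisible(x)
}
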