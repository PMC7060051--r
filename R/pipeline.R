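# Analysis configuration and the end-to-end pipeline driver used by the
# numbered analysis scripts and the acceptance script.

#' Analysis configuration
#'
#' Collects every analysis constant in one place. Constants that correspond
#' to a number stated with the original experimental design default to that
#' value.
#'
#' @param sigma_ms Gaussian smoothing sd (20; 10 is the documented alternate).
#' @param lag_ms behavioral lag (25; alternates 0, 50).
#' @param lambda ridge penalty, `NULL` for GCV.
#' @param n_iter bootstrap iterations (1000).
#' @param group_size units per relative-direction bin in the subspace
#'   bootstrap (20).
#' @param subpop_group_size per-bin group size for per-subpopulation angles.
#' @param seed master analysis seed.
#' @param prep_window,single_trial_prep_window early-fixation reference
#'   windows, ms after fixation onset (captions state 151-250; the
#'   single-trial analysis paragraph states 150-250 - both kept, logged).
#' @param purs_window pursuit epoch, ms after motion onset (51-150).
#' @param fixation_trim_ms samples dropped from the start/end of fixation
#'   averages (150, 50).
#' @param pulse_window_ms response window after pulse onset (200).
#' @param pulse_bin_ms fixation-time bin width for gain profiles (200).
#' @param saccade_speed_threshold,saccade_accel_threshold rejection
#'   thresholds (30 deg/s, 1000 deg/s^2).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(sigma_ms = 20, lag_ms = 25, lambda = NULL,
                            n_iter = 1000, group_size = 20,
                            subpop_group_size = 5, seed = 1,
                            prep_window = c(151, 250),
                            single_trial_prep_window = c(150, 250),
                            purs_window = c(51, 150),
                            fixation_trim_ms = c(150, 50),
                            pulse_window_ms = 200, pulse_bin_ms = 200,
                            saccade_speed_threshold = 30,
                            saccade_accel_threshold = 1000) {
  structure(list(sigma_ms = sigma_ms, lag_ms = lag_ms, lambda = lambda,
                 n_iter = n_iter, group_size = group_size,
                 subpop_group_size = subpop_group_size, seed = seed,
                 prep_window = prep_window,
                 single_trial_prep_window = single_trial_prep_window,
                 purs_window = purs_window,
                 fixation_trim_ms = fixation_trim_ms,
                 pulse_window_ms = pulse_window_ms,
                 pulse_bin_ms = pulse_bin_ms,
                 saccade_speed_threshold = saccade_speed_threshold,
                 saccade_accel_threshold = saccade_accel_threshold),
            class = "analysis_config")
}

#' Write an analysis configuration to YAML
#'
#' @param config an [analysis_config()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' Unknown fields are an error rather than silently dropped.
#'
#' @param path YAML file written by [write_analysis_config()] (or edited by
#'   hand).
#' @return an [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    stop(sprintf("unknown analysis_config field(s): %s",
                 paste(extra, collapse = ", ")))
  }
  raw$lambda <- raw$lambda %||% NULL
  do.call(analysis_config, raw)
}

# toward/away preparatory input for demixed PCA: units contributing a
# single-direction block both within 90 deg of the preferred direction and
# farther than 90 deg. Returns units x (2 x 1400) matrix plus labels.
#' Build the toward/away matrix for demixed PCA
#'
#' Pairs, per unit, preparatory fixation averages from single-direction
#' blocks run toward (relative direction < 90 deg) and away (> 90 deg) from
#' the unit's preferred direction; units lacking either side (for instance
#' purely orthogonal blocks) are dropped.
#'
#' @param pop a `pseudopopulation`.
#' @return list with `X` (units x 2800), `condition_labels`
#'   (toward/away per column), `units`.
#' @export
build_dpca_input <- function(pop) {
  rel <- circ_diff(pop$meta$pref_direction, pop$meta$block_direction)
  side <- ifelse(rel < 90, "toward", ifelse(rel > 90, "away", NA))
  keep_units <- intersect(
    unique(pop$meta$unit_id[which(side == "toward")]),
    unique(pop$meta$unit_id[which(side == "away")]))
  if (length(keep_units) < 2) stop("need units with both toward and away blocks")
  nt <- ncol(pop$N_prep)
  X <- t(vapply(keep_units, function(u) {
    tw <- which(pop$meta$unit_id == u & side == "toward")
    aw <- which(pop$meta$unit_id == u & side == "away")
    c(colMeans(pop$N_prep[tw, , drop = FALSE]),
      colMeans(pop$N_prep[aw, , drop = FALSE]))
  }, numeric(2 * nt)))
  list(X = X, condition_labels = rep(c("toward", "away"), each = nt),
       units = keep_units)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages: `simulate` (population + pulse experiment), `preprocess`,
#' `fit-readout`, `predict-prep` (projection + single-trial bootstrap),
#' `subspace` (bootstrap angle, loading ratios, dip test, subpopulations),
#' `dpca`, `pulse-analysis`. Later stages reuse the outputs of earlier ones;
#' requesting a stage whose inputs are missing from `state` is an error.
#'
#' @param config an [analysis_config()].
#' @param synth a [synthetic_config()].
#' @param stages character vector of stages to run (default all).
#' @param state optionally, the bundle from a previous partial run.
#' @param out_dir optional directory for CSV outputs and a JSON manifest.
#' @return results bundle (list), invisibly extended `state`.
#' @export
run_pipeline <- function(config = analysis_config(),
                         synth = synthetic_config(),
                         stages = c("simulate", "preprocess", "fit-readout",
                                    "predict-prep", "subspace", "dpca",
                                    "pulse-analysis"),
                         state = list(), out_dir = NULL) {
  log_msg <- function(...) message(sprintf(...))
  need <- function(field, stage) {
    if (is.null(state[[field]])) {
      stop(sprintf("stage '%s' needs '%s' from an earlier stage", stage, field))
    }
    state[[field]]
  }
  seeds_used <- state$seeds_used %||% list()
  if ("simulate" %in% stages) {
    log_msg("simulate: seed %d, %d units", synth$seed, synth$n_neurons)
    state$dataset <- generate_population(synth)
    state$pulses <- generate_pulse_experiment(synth)
    seeds_used$simulate <- synth$seed
  }
  if ("preprocess" %in% stages) {
    ds <- need("dataset", "preprocess")
    log_msg("preprocess: sigma = %d ms, lag = %d ms", config$sigma_ms,
            config$lag_ms)
    state$pop <- build_pseudopopulation(ds$sessions,
                                        sigma_ms = config$sigma_ms,
                                        lag_ms = config$lag_ms)
  }
  if ("fit-readout" %in% stages) {
    pop <- need("pop", "fit-readout")
    state$model <- fit_readout(pop$N_8D, pop$E, lambda = config$lambda,
                               lag_ms = config$lag_ms)
    log_msg("fit-readout: lambda = %.4g", state$model$lambda)
    state$cv <- cross_validate(state$model, pop$N_purs_cv, pop$E_purs)
  }
  if ("predict-prep" %in% stages) {
    pop <- need("pop", "predict-prep")
    model <- need("model", "predict-prep")
    state$prep_prediction <- predict_preparatory(model, pop$N_1D)
    st_seed <- child_seed(config$seed, 3L)
    seeds_used$single_trial <- st_seed
    state$single_trial <- single_trial_bootstrap(
      pop$trial_prep, pop$meta$range, model, n_iter = config$n_iter,
      seed = st_seed)
    log_msg("predict-prep: mean speed %.2f deg/s, mean direction %.1f deg",
            state$single_trial$mean_speed, state$single_trial$mean_direction)
  }
  if ("subspace" %in% stages) {
    pop <- need("pop", "subspace")
    bs_seed <- child_seed(config$seed, 4L)
    seeds_used$subspace <- bs_seed
    state$subspace <- bootstrap_subspace(pop, n_iter = config$n_iter,
                                         group_size = config$group_size,
                                         seed = bs_seed)
    log_msg("subspace: mean angle %.1f deg [%.1f, %.1f]",
            state$subspace$mean_angle, state$subspace$ci95[1],
            state$subspace$ci95[2])
    ratios <- state$subspace$mean_loading_ratios
    dip_seed <- child_seed(config$seed, 5L)
    seeds_used$dip <- dip_seed
    state$ratio_dip <- hartigan_dip(ratios[is.finite(ratios)],
                                    n_null = config$n_iter, seed = dip_seed)
    state$labels <- loading_ratio_split(ratios)
    sp_seed <- child_seed(config$seed, 6L)
    seeds_used$subpop <- sp_seed
    state$subpops <- subpopulation_analysis(
      pop, state$labels, group_size = config$subpop_group_size,
      n_iter = config$n_iter, seed = sp_seed, lambda = config$lambda)
  }
  if ("dpca" %in% stages) {
    pop <- need("pop", "dpca")
    inp <- tryCatch(build_dpca_input(pop), error = function(e) {
      log_msg("dpca: skipped (%s)", conditionMessage(e))
      NULL
    })
    if (!is.null(inp)) {
    state$dpca <- fit_dpca(inp$X, inp$condition_labels, n_components = 10,
                           regularization = 0)
    vf <- state$dpca$variance / state$dpca$total_variance
    log_msg("dpca: top-3 variance %.1f%%, marginalizations %s",
            100 * sum(vf[seq_len(min(3, length(vf)))]),
            paste(state$dpca$marginalization[seq_len(min(3, length(vf)))],
                  collapse = "/"))
    }
  }
  if ("pulse-analysis" %in% stages) {
    pl <- need("pulses", "pulse-analysis")
    ex <- extract_pulse_responses(
      pl, speed_threshold = config$saccade_speed_threshold,
      accel_threshold = config$saccade_accel_threshold)
    state$pulse_responses <- ex
    rdir <- ex$responses[ex$responses$experiment == "direction", ]
    state$gain <- gain_timecourse(rdir, bin_ms = config$pulse_bin_ms)
    rctx <- ex$responses[ex$responses$experiment == "context", ]
    if (nrow(rctx) > 0) {
      fast <- tapply(rctx$response[rctx$context == "fast"],
                     rctx$session[rctx$context == "fast"], mean)
      slow <- tapply(rctx$response[rctx$context == "slow"],
                     rctx$session[rctx$context == "slow"], mean)
      common <- intersect(names(fast), names(slow))
      state$context <- context_effect(fast[common], slow[common])
      log_msg("pulse-analysis: fast %.2f vs slow %.2f deg/s, d = %.2f",
              state$context$means["fast"], state$context$means["slow"],
              state$context$d)
    }
  }
  state$seeds_used <- seeds_used
  state$config <- config
  state$synth_config <- state$synth_config %||% synth
  if (!is.null(out_dir)) .write_pipeline_outputs(state, out_dir)
  invisible(state)
}

.write_pipeline_outputs <- function(state, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, name) {
    utils::write.csv(d, file.path(out_dir, name), row.names = FALSE)
  }
  if (!is.null(state$pop)) {
    wcsv(state$pop$meta, "pseudopopulation_meta.csv")
  }
  if (!is.null(state$model)) {
    wcsv(data.frame(unit = seq_along(state$model$weight_magnitudes),
                    w_h = state$model$W[1, ], w_v = state$model$W[2, ],
                    magnitude = state$model$weight_magnitudes),
         "readout_weights.csv")
  }
  if (!is.null(state$single_trial)) {
    wcsv(data.frame(direction = state$single_trial$direction_distribution,
                    speed = state$single_trial$speed_distribution),
         "single_trial_bootstrap.csv")
  }
  if (!is.null(state$subspace)) {
    wcsv(data.frame(angle = state$subspace$angle_distribution),
         "subspace_angles.csv")
    wcsv(data.frame(row = seq_along(state$subspace$mean_loading_ratios),
                    ratio = state$subspace$mean_loading_ratios,
                    label = state$labels),
         "loading_ratios.csv")
  }
  if (!is.null(state$gain)) {
    wcsv(state$gain$slopes, "gain_slopes.csv")
    wcsv(state$gain$binned, "gain_binned.csv")
  }
  manifest <- list(
    seeds = state$seeds_used,
    config = unclass(state$config),
    synth_config = unclass(state$synth_config)[
      setdiff(names(state$synth_config), "block_specs")],
    version = as.character(utils::packageVersion("pursuitprep")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
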