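# Plain-text dataset serialization (CSV tables plus a JSON manifest) and
# tolerant loaders for per-figure source-data style tables.

#' Write a dataset to a plain-text directory container
#'
#' Layout: `manifest.json` (type, session index, config echo) and one long
#' CSV per session under `sessions/` with per-sample rows.
#'
#' @param dataset a `synthetic_dataset` or `behavioral_session_set`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(file.path(path, "sessions"), recursive = TRUE,
             showWarnings = FALSE)
  if (inherits(dataset, "synthetic_dataset")) {
    ids <- character(0)
    for (s in dataset$sessions) {
      id <- paste0(s$unit_id, "__", s$block_id)
      ids <- c(ids, id)
      rows <- lapply(seq_along(s$trials), function(k) {
        tr <- s$trials[[k]]
        data.frame(trial = k, t = seq_along(tr$rate) - 1L,
                   rate = tr$rate, eye_h = tr$eye[1, ], eye_v = tr$eye[2, ],
                   direction = tr$direction, speed = tr$speed,
                   contrast = tr$contrast, motion_onset = tr$motion_onset)
      })
      utils::write.csv(do.call(rbind, rows),
                       file.path(path, "sessions", paste0(id, ".csv")),
                       row.names = FALSE)
    }
    manifest <- list(
      type = "neural",
      sessions = lapply(dataset$sessions, function(s) {
        list(id = paste0(s$unit_id, "__", s$block_id), unit_id = s$unit_id,
             block_id = s$block_id, block_type = s$block_type,
             block_direction = s$block_direction, context = s$context)
      }),
      config = dataset$config[setdiff(names(dataset$config), "block_specs")])
  } else if (inherits(dataset, "behavioral_session_set")) {
    for (s in dataset$sessions) {
      rows <- lapply(seq_along(s$trials), function(k) {
        tr <- s$trials[[k]]
        data.frame(trial = k, t = seq_along(tr$speed) - 1L, speed = tr$speed,
                   pulse_onset = tr$pulse_onset,
                   direction_class = tr$direction_class %||% NA_character_,
                   context = tr$context, has_pulse = tr$has_pulse,
                   motion_onset = tr$motion_onset)
      })
      utils::write.csv(do.call(rbind, rows),
                       file.path(path, "sessions", paste0(s$session_id, ".csv")),
                       row.names = FALSE)
    }
    manifest <- list(
      type = "behavioral",
      sessions = lapply(dataset$sessions, function(s) {
        list(id = s$session_id, experiment = s$experiment,
             context = s$context)
      }))
  } else stop("unsupported dataset type")
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Validates event ordering on load: trials whose fixation duration falls
#' outside 800-1600 ms are reported with a warning naming the session and
#' trial.
#'
#' @param path dataset directory.
#' @return list of `recording_session` (neural) or a
#'   `behavioral_session_set` (behavioral).
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json: not a dataset directory")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (identical(manifest$type, "neural")) {
    idx <- manifest$sessions
    sessions <- lapply(seq_len(nrow(idx)), function(i) {
      d <- utils::read.csv(file.path(path, "sessions",
                                     paste0(idx$id[i], ".csv")))
      trials <- lapply(split(d, d$trial), function(td) {
        td <- td[order(td$t), ]
        tf <- td$motion_onset[1]
        if (tf < 800 || tf > 1600) {
          warning(sprintf("session %s trial %d: fixation duration %d ms outside 800-1600",
                          idx$id[i], td$trial[1], tf), call. = FALSE)
        }
        list(direction = td$direction[1], speed = td$speed[1],
             contrast = td$contrast[1], motion_onset = tf,
             rate = td$rate, eye = rbind(td$eye_h, td$eye_v))
      })
      structure(list(unit_id = idx$unit_id[i], block_id = idx$block_id[i],
                     block_type = idx$block_type[i],
                     block_direction = idx$block_direction[i],
                     context = idx$context[i],
                     trials = unname(trials)), class = "recording_session")
    })
    sessions
  } else if (identical(manifest$type, "behavioral")) {
    idx <- manifest$sessions
    sessions <- lapply(seq_len(nrow(idx)), function(i) {
      d <- utils::read.csv(file.path(path, "sessions",
                                     paste0(idx$id[i], ".csv")))
      trials <- lapply(split(d, d$trial), function(td) {
        td <- td[order(td$t), ]
        list(speed = td$speed, pulse_onset = td$pulse_onset[1],
             direction_class = td$direction_class[1],
             context = td$context[1],
             has_pulse = isTRUE(td$has_pulse[1]) | td$has_pulse[1] == "TRUE",
             motion_onset = td$motion_onset[1])
      })
      list(session_id = idx$id[i], experiment = idx$experiment[i],
           context = idx$context[i], trials = unname(trials))
    })
    structure(list(sessions = sessions), class = "behavioral_session_set")
  } else stop("manifest has unknown dataset type")
}

#' Load a per-unit modulation table from CSV
#'
#' Tolerates column-name variants through an explicit mapping; columns not
#' covered by the mapping are an error, never a guess.
#'
#' @param path CSV file with one row per unit/sample.
#' @param column_map named character vector mapping roles `unit`, `prep`,
#'   `purs` (optionally `monkey`, `direction`) to the file's column names.
#' @return data frame with standardized columns.
#' @export
read_modulation_table <- function(path,
                                  column_map = c(unit = "unit",
                                                 prep = "prep_modulation",
                                                 purs = "purs_modulation")) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("unit", "prep", "purs")
  if (!all(need %in% names(column_map))) {
    stop("column_map must define roles: unit, prep, purs")
  }
  missing_cols <- setdiff(unname(column_map), names(d))
  if (length(missing_cols) > 0) {
    stop(sprintf("mapped column(s) not in file: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  unmapped <- setdiff(names(d), unname(column_map))
  if (length(unmapped) > 0) {
    stop(sprintf("unmapped column(s) in file: %s (extend column_map)",
                 paste(unmapped, collapse = ", ")))
  }
  out <- data.frame(unit = d[[column_map[["unit"]]]],
                    prep = as.numeric(d[[column_map[["prep"]]]]),
                    purs = as.numeric(d[[column_map[["purs"]]]]))
  for (role in setdiff(names(column_map), need)) {
    out[[role]] <- d[[column_map[[role]]]]
  }
  out
}
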