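# Pulse-probe behavioral analysis: saccade rejection, peak-response
# extraction, gain time courses and slopes across fixation, speed-context
# contrasts, and the regression of behavioral gain on preparatory firing.

#' Detect saccadic intervals in an eye trace
#'
#' Maximal intervals where speed exceeds `speed_threshold` or the absolute
#' central-difference acceleration exceeds `accel_threshold` (strict
#' inequalities), each padded by 10 ms on both sides and merged.
#'
#' @param trace eye-speed (or velocity-component) trace, 1 kHz.
#' @param speed_threshold deg/s (default 30).
#' @param accel_threshold deg/s^2 (default 1000).
#' @param pad_ms padding per side (default 10).
#' @return two-column matrix of interval start/end sample times in ms
#'   (0-based); zero rows when the trace is quiet.
#' @export
detect_saccades <- function(trace, speed_threshold = 30,
                            accel_threshold = 1000, pad_ms = 10) {
  n <- length(trace)
  if (n < 3) stop("trace must have at least 3 samples")
  acc <- c(0, (trace[3:n] - trace[1:(n - 2)]) / 2, 0) * 1000  # deg/s^2
  hit <- abs(trace) > speed_threshold | abs(acc) > accel_threshold
  if (!any(hit)) return(matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("from", "to"))))
  d <- diff(c(FALSE, hit, FALSE))
  from <- which(d == 1) - 1L   # 0-based ms
  to <- which(d == -1) - 2L
  from <- pmax(0, from - pad_ms)
  to <- pmin(n - 1L, to + pad_ms)
  # merge overlapping padded intervals
  keep_from <- from[1]; out <- NULL
  cur_to <- to[1]
  if (length(from) > 1) {
    for (k in 2:length(from)) {
      if (from[k] <= cur_to + 1) {
        cur_to <- max(cur_to, to[k])
      } else {
        out <- rbind(out, c(keep_from, cur_to))
        keep_from <- from[k]; cur_to <- to[k]
      }
    }
  }
  out <- rbind(out, c(keep_from, cur_to))
  colnames(out) <- c("from", "to")
  out
}

#' Peak eye-speed response to a pulse
#'
#' Maximum of the eye-speed trace over the 200 ms following pulse onset
#' (window `(pulse_onset, pulse_onset + 200]`).
#'
#' @param trial list with `speed` (trace, 1 kHz from fixation onset) and
#'   `pulse_onset` (ms).
#' @return peak speed, deg/s.
#' @export
pulse_response <- function(trial) {
  po <- trial$pulse_onset
  if (is.na(po)) stop("trial has no pulse")
  idx <- (po + 1):(po + 200) + 1L
  if (max(idx) > length(trial$speed)) stop("response window truncated by trial end")
  max(trial$speed[idx])
}

#' Gain time course and per-session slopes
#'
#' Ordinary least-squares slope of peak response against pulse time (in
#' seconds from fixation onset), per session and pulse-direction class, plus
#' binned means over 200-ms fixation-time bins (reported at bin centers).
#'
#' @param responses data frame with columns `session`, `class`, `time_ms`,
#'   `response`.
#' @param bin_ms bin width for display means (default 200).
#' @param bin_range fixation-time range tiled by the bins (default
#'   `c(550, 1350)` ms).
#' @return object of class `gain_profile`: `slopes` (per session x class,
#'   deg/s per s), `binned` (mean response per class x bin center),
#'   `by_class` (mean slope, sd, signed-rank test per class).
#' @export
gain_timecourse <- function(responses, bin_ms = 200,
                            bin_range = c(550, 1350)) {
  stopifnot(all(c("session", "class", "time_ms", "response") %in%
                  names(responses)))
  sl <- list()
  for (ss in unique(responses$session)) {
    for (cl in unique(responses$class)) {
      d <- responses[responses$session == ss & responses$class == cl, ]
      if (nrow(d) < 2 || length(unique(d$time_ms)) < 2) {
        if (nrow(d) > 0) {
          stop(sprintf("session %s, class %s: slope undefined with %d pulse time(s)",
                       ss, cl, length(unique(d$time_ms))))
        }
        next
      }
      t_s <- d$time_ms / 1000
      sl[[length(sl) + 1L]] <- data.frame(
        session = ss, class = cl,
        slope = stats::cov(t_s, d$response) / stats::var(t_s),
        n = nrow(d), stringsAsFactors = FALSE)
    }
  }
  slopes <- do.call(rbind, sl)
  breaks <- seq(bin_range[1], bin_range[2], by = bin_ms)
  centers <- breaks[-length(breaks)] + bin_ms / 2
  bin <- findInterval(responses$time_ms, breaks, rightmost.closed = TRUE)
  bin[bin < 1 | bin >= length(breaks)] <- NA
  binned <- stats::aggregate(
    response ~ class + bin,
    data = cbind(responses, bin = bin), FUN = mean)
  binned$time_ms <- centers[binned$bin]
  by_class <- do.call(rbind, lapply(split(slopes, slopes$class), function(d) {
    wt <- wilcoxon_tests(d$slope, paired = TRUE)
    data.frame(class = d$class[1], mean_slope = mean(d$slope),
               sd_slope = stats::sd(d$slope), n = nrow(d),
               p = wt$p, z = wt$z, stringsAsFactors = FALSE)
  }))
  structure(list(slopes = slopes, binned = binned, by_class = by_class,
                 bin_ms = bin_ms, bin_range = bin_range),
            class = "gain_profile")
}

#' Fast- vs slow-context effect on pulse responses
#'
#' Paired two-sided Wilcoxon signed-rank test across sessions, with the z
#' statistic, paired Cohen's d, and the two context means.
#'
#' @param fast_responses,slow_responses per-session mean peak responses,
#'   paired by position.
#' @return list with `p`, `z`, `d`, `means` (named fast/slow), `n`.
#' @export
context_effect <- function(fast_responses, slow_responses) {
  if (length(fast_responses) != length(slow_responses)) {
    stop("context responses must be paired per session")
  }
  wt <- wilcoxon_tests(fast_responses, slow_responses, paired = TRUE)
  list(p = wt$p, z = wt$z,
       d = cohens_d(fast_responses, slow_responses, paired = TRUE),
       means = c(fast = mean(fast_responses), slow = mean(slow_responses)),
       n = length(fast_responses), degenerate = wt$degenerate)
}

#' Regression of behavioral gain on preparatory firing rate
#'
#' Per-neuron least-squares slope of the eye-speed response against the
#' neuron's preparatory firing rate across matched fixation times, with the
#' population mean and a sign test on the slopes.
#'
#' @param session_gain_by_time mean behavioral response per fixation-time
#'   point (deg/s).
#' @param neuron_rate_by_time neurons x time-points matrix of preparatory
#'   rates (spikes/s) at the same fixation times.
#' @return list with `slopes` (degrees/spike per neuron), `mean_slope`,
#'   `sign_test_p`, `n`.
#' @export
gain_rate_regression <- function(session_gain_by_time, neuron_rate_by_time) {
  g <- as.numeric(session_gain_by_time)
  if (length(g) < 2) stop("need at least 2 fixation times")
  M <- as.matrix(neuron_rate_by_time)
  if (ncol(M) != length(g)) stop("rate matrix columns must match fixation times")
  slopes <- apply(M, 1, function(r) {
    vr <- stats::var(r)
    if (!is.finite(vr) || vr == 0) return(NA_real_)
    stats::cov(r, g) / vr
  })
  ok <- is.finite(slopes)
  st <- stats::binom.test(sum(slopes[ok] > 0), sum(ok))
  list(slopes = slopes, mean_slope = mean(slopes[ok]),
       sign_test_p = st$p.value, n = sum(ok))
}

#' Saccade rejection and response extraction for pulse sessions
#'
#' Applies saccade detection to every pulse trial, discards trials whose
#' detected intervals intersect the window from pulse onset to 200 ms after
#' pulse onset, and extracts peak responses for the remainder.
#'
#' @param session_set a `behavioral_session_set` from
#'   [generate_pulse_experiment()] (or the same structure read from disk).
#' @param speed_threshold,accel_threshold saccade detection thresholds.
#' @return list with `responses` (data frame: session, experiment, context,
#'   class, time_ms, response), `n_rejected`, `n_kept`.
#' @export
extract_pulse_responses <- function(session_set, speed_threshold = 30,
                                    accel_threshold = 1000) {
  rows <- list(); n_rej <- 0L
  for (s in session_set$sessions) {
    for (tr in s$trials) {
      if (!isTRUE(tr$has_pulse)) next
      iv <- detect_saccades(tr$speed, speed_threshold, accel_threshold)
      win <- c(tr$pulse_onset, tr$pulse_onset + 200)
      bad <- nrow(iv) > 0 && any(iv[, "to"] >= win[1] & iv[, "from"] <= win[2])
      if (bad) { n_rej <- n_rej + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        session = s$session_id, experiment = s$experiment,
        context = tr$context, class = tr$direction_class,
        time_ms = tr$pulse_onset, response = pulse_response(tr),
        stringsAsFactors = FALSE)
    }
  }
  responses <- do.call(rbind, rows)
  list(responses = responses, n_rejected = n_rej,
       n_kept = if (is.null(responses)) 0L else nrow(responses))
}

#' @export
print.gain_profile <- function(x, ...) {
  cat("gain_profile: per-session slopes (deg/s per s)\n")
  print(x$by_class, row.names = FALSE)
  invisible(x)
}
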