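#!/usr/bin/env Rscript
# Stage 6: pulse-probe visuomotor gain.
#
# Rejects saccade-contaminated trials, extracts peak eye-speed responses to
# the 5 deg/s, 50 ms pulses, fits per-session response-vs-fixation-time
# slopes by pulse direction, contrasts fast vs slow speed contexts
# (paired signed-rank test, Cohen's d), and regresses behavioral gain on
# preparatory firing rate across matched fixation-time bins.

library(pursuitprep)

pulses <- readRDS("scratch/pulses.rds")
ex <- extract_pulse_responses(pulses)
message(sprintf("%d pulse trials kept, %d rejected for saccades",
                ex$n_kept, ex$n_rejected))

rdir <- ex$responses[ex$responses$experiment == "direction", ]
g <- gain_timecourse(rdir)
print(g)

rctx <- ex$responses[ex$responses$experiment == "context", ]
fast <- tapply(rctx$response[rctx$context == "fast"],
               rctx$session[rctx$context == "fast"], mean)
slow <- tapply(rctx$response[rctx$context == "slow"],
               rctx$session[rctx$context == "slow"], mean)
common <- intersect(names(fast), names(slow))
ce <- context_effect(fast[common], slow[common])
message(sprintf(
  "context effect: fast %.2f vs slow %.2f deg/s, d = %.2f, z = %.2f, p = %.2g",
  ce$means[["fast"]], ce$means[["slow"]], ce$d, ce$z, ce$p))

# behavioral gain vs preparatory rate across 200-ms fixation-time bins
pop <- readRDS("scratch/pop.rds")
centers <- seq(650, 1250, by = 200)
beh <- vapply(centers, function(tc) {
  sel <- rdir$class == "same" & abs(rdir$time_ms - tc) <= 100
  mean(rdir$response[sel])
}, numeric(1))
inc <- pop$meta$prep_mod > 0
rate_by_bin <- vapply(centers, function(tc) {
  idx <- (tc - 100):(tc - 1) - 150 + 1
  rowMeans(pop$N_prep[inc, idx, drop = FALSE])
}, numeric(sum(inc)))
gr <- gain_rate_regression(beh, rate_by_bin)
message(sprintf(
  "gain vs preparatory rate: mean slope %.4f deg/spike over %d increase rows (sign-test p = %.2g)",
  gr$mean_slope, gr$n, gr$sign_test_p))

write.csv(g$slopes, "results/gain_slopes.csv", row.names = FALSE)
write.csv(g$binned, "results/gain_binned.csv", row.names = FALSE)
write.csv(data.frame(session = common, fast = as.numeric(fast[common]),
                     slow = as.numeric(slow[common])),
          "results/context_responses.csv", row.names = FALSE)
message("wrote results/gain_slopes.csv, results/gain_binned.csv, results/context_responses.csv")
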