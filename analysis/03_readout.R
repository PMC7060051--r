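#!/usr/bin/env Rscript
# Stage 3: the movement-potent readout.
#
# Fits the ridge readout W from the 8-direction block (E = W N_8D),
# cross-validates it on the held-out single-direction pursuit conditions,
# projects preparatory activity through it (PE = W N_1D), and runs the
# 1000-iteration single-trial bootstrap of preparatory predictions. The
# planted weights are available, so the recovery error is reported too.

library(pursuitprep)

pop <- readRDS("scratch/pop.rds")
truth <- ground_truth(readRDS("scratch/dataset.rds"))

model <- fit_readout(pop$N_8D, pop$E)
message(sprintf("ridge penalty (GCV): %.3g", model$lambda))
message(sprintf("planted-weight relative error: %.3f",
                sqrt(sum((model$W - truth$W_true)^2) / sum(truth$W_true^2))))

cv <- cross_validate(model, pop$N_purs_cv, pop$E_purs)
message(sprintf("cross-validation (horizontal): slope %.3f, r2 %.3f",
                cv$slope[["h"]], cv$r2[["h"]]))

pred <- predict_preparatory(model, pop$N_1D)
late <- ncol(pop$N_1D) - (0:99)
message(sprintf("late-fixation prediction: %.2f deg/s toward %.1f deg",
                mean(pred$PS[late]), mean(pred$direction[late])))

st <- single_trial_bootstrap(pop$trial_prep, pop$meta$range, model,
                             n_iter = 1000, seed = 3)
message(sprintf(
  "single-trial bootstrap: mean direction %.1f deg [%.1f, %.1f], mean speed %.2f deg/s",
  st$mean_direction, st$ci95_direction[1], st$ci95_direction[2],
  st$mean_speed))

saveRDS(model, "scratch/model.rds")
write.csv(data.frame(row = seq_along(model$weight_magnitudes),
                     w_h = model$W[1, ], w_v = model$W[2, ],
                     magnitude = model$weight_magnitudes),
          "results/readout_weights.csv", row.names = FALSE)
write.csv(data.frame(direction = st$direction_distribution,
                     speed = st$speed_distribution),
          "results/single_trial_bootstrap.csv", row.names = FALSE)
message("wrote results/readout_weights.csv, results/single_trial_bootstrap.csv")
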