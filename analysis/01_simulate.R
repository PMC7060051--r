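#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Builds the neural pseudo-session dataset (192 units, balanced
# relative-direction bins, mixed-speed single-direction blocks) and the
# pulse-probe behavioral sessions (30 direction experiments, 26 paired
# fast/slow context experiments), all from one master seed. The heavy raw
# traces go to scratch/ as an R image; summary tables go to results/.

library(pursuitprep)

seed <- 1
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

synth <- synthetic_config(n_neurons = 192, noise_sd = 2,
                          trials_per_condition = 4, seed = seed)
message("generating population: ", synth$n_neurons, " units, seed ", seed)
dataset <- generate_population(synth)
pulses <- generate_pulse_experiment(synth)

truth <- ground_truth(dataset)
message(sprintf("planted: theta_true = %.1f deg, %d/%d subpopulation-2 rows",
                truth$theta_true, sum(truth$subpop_labels == 2),
                length(truth$subpop_labels)))

saveRDS(dataset, "scratch/dataset.rds")
saveRDS(pulses, "scratch/pulses.rds")

write.csv(data.frame(
  row = seq_along(truth$unit_index),
  unit = truth$unit_index,
  preferred_direction = truth$preferred_directions,
  block_direction = truth$block_directions,
  relative_direction = truth$relative_directions,
  subpop = truth$subpop_labels,
  prep_amplitude = truth$prep_amplitudes,
  purs_amplitude = truth$purs_amplitudes),
  "results/planted_truth.csv", row.names = FALSE)
message("wrote results/planted_truth.csv and scratch/{dataset,pulses}.rds")
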