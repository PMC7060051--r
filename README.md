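# pursuitprep

Population-level analyses of preparatory activity in the smooth eye
movement region of the frontal eye fields (FEF~SEM~) and of the
behavioral quantity it parallels, preparatory modulation of visual-motor
gain in smooth pursuit — implemented as a tested R package with a
synthetic-data generator that plants every quantity the analyses
estimate, so that each stage is validated by parameter recovery.

Who this is for: researchers in oculomotor and population-dynamics
neurophysiology who want the movement-null vs movement-potent analyses
(ridge readout, subspace angles, demixed PCA, loading-ratio
decomposition, pulse-probe gain) as reusable, verifiable code.

## The analyses

* **Movement-potent readout.** The optimal linear model from population
  firing rate to eye velocity, `E = W N_8D`, fit by ridge regression on
  the 8-direction pursuit block (rates smoothed with a 20-ms Gaussian,
  rotated into each unit's single-direction frame, mean-centered and
  range-normalized; eye velocity shifted forward 25 ms), cross-validated
  on held-out single-direction conditions, and applied to preparatory
  activity, `PE = W N_1D`. A single-trial bootstrap (1000 iterations,
  fixation-duration-matched sampling) gives distributions of the
  predicted preparatory direction and speed.
* **Subspace geometry.** PCA of the preparatory and pursuit epochs (rows
  normalized to unit range, centered), the angle
  `theta = arccos(PC_Prep1 . PC_Purs1 / |PC_Prep1||PC_Purs1|)`, a
  bootstrap over balanced 160-unit pseudo-populations (20 units per
  relative-direction bin, without replacement), per-unit loading ratios
  `PC_Prep1 / PC_Purs1`, Hartigan's dip test for their bimodality, and
  the subpopulation decomposition at ratio zero.
* **Demixed PCA.** Two-marginalization dPCA (direction-independent vs
  direction-dependent) of preparatory activity for units recorded both
  toward and away from their preferred direction, solved by reduced-rank
  regression via the SVD, with exact marginalization conservation.
* **Pulse-probe gain.** Saccade rejection, peak eye-speed responses to
  5 deg/s, 50 ms target-motion pulses, per-session response-vs-time
  slopes by pulse direction, fast/slow context contrasts (signed-rank z,
  Cohen's d), and the per-neuron regression of behavioral gain on
  preparatory firing rate.
* **Statistics.** Self-contained Spearman, Wilcoxon (exact small-sample
  enumeration, z with continuity correction), Cohen's d, percentile
  bootstrap intervals, and an exact Hartigan dip statistic with a
  Monte-Carlo uniform null.

The synthetic generator (see the methods vignette,
`vignettes/preparatory-dynamics.Rmd`) plants von Mises pursuit tuning
with transient/sustained heterogeneity, subpopulation-specific
preparatory ramps, a linear readout that generates the eye velocity, a
target loading-ratio geometry, and a time- and direction-dependent gain
`G(t, delta) = g0 + a_dir cos(delta) + (b0 + b1 cos(delta)) t` — all
recoverable exactly when noise is off.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (192 units, 4 trials per condition, rate noise 2 spikes/s, seed 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_readout.R
Rscript analysis/04_subspace.R
Rscript analysis/05_dpca.R
Rscript analysis/06_behavior_gain.R
```

Output of stages 3 and 4 on this configuration:

```
ridge penalty (GCV): 6.27
planted-weight relative error: 0.045
cross-validation (horizontal): slope 1.001, r2 1.000
late-fixation prediction: 3.85 deg/s toward -0.3 deg
single-trial bootstrap: mean direction -0.2 deg [-0.7, 0.3], mean speed 2.83 deg/s

angle(PC_Prep1, PC_Purs1): mean 60.8 deg, 95% CI [57.6, 63.8] (planted 60.0)
Hartigan dip test: dip = 0.0564, p = 0.000999 (n = 192, 1000 null sims)
subpopulation 1 full-sample angle: 23.1 deg (n = 143)
subpopulation 2 full-sample angle: 148.8 deg (n = 49)
```

Reading these numbers: the fitted readout recovers the planted weights
to 4.5% under noise and predicts the held-out pursuit eye velocity with
unit slope; passed through the same weights, *preparatory* activity
predicts a non-zero eye movement (2.8 deg/s) aimed at the upcoming
target direction — preparatory activity does not hide in movement-null
dimensions. At the same time the preparatory and pursuit principal
components sit at ~61 deg (neither aligned nor orthogonal: a partial
reorganization), the loading-ratio distribution is significantly bimodal,
and splitting at ratio zero isolates a majority subpopulation whose
preparatory and pursuit patterns nearly coincide (23 deg) and a minority
whose pattern reverses (149 deg). Stage 6 then shows the behavioral
parallel: pulse responses grow across fixation with slopes ordered
same > orthogonal > opposite (1.03, 0.74, 0.40 deg/s per s here), and
fast-context responses exceed slow-context ones (3.20 vs 2.40 deg/s,
d = 1.48).

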