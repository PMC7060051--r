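---
title: "Preparatory population dynamics and visuomotor gain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparatory population dynamics and visuomotor gain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

During fixation before a predictable target motion, neurons in the smooth
eye movement region of the frontal eye fields (FEF~SEM~) ramp up their
firing although the eyes do not move. Two population-level accounts of how
preparation can proceed without movement make different predictions. Under
the movement-null hypothesis, preparatory activity is confined to
dimensions of population state space that a downstream linear readout
cannot see. Under the gain hypothesis, the population's output is not a
movement command at all but a gain on visual-motor transmission, so
preparatory output is free to grow; it is visible to the readout but there
is no visual drive for it to amplify. This package implements the
population analyses that distinguish the two accounts, together with a
synthetic-data generator that plants every quantity the analyses estimate,
so that each stage is verified by parameter recovery rather than by
inspection.

## The linear readout and the movement-potent projection

The movement-potent dimensions are defined by the optimal linear model
from population firing rate to eye velocity,

  E = W N_8D,

where `N_8D` is the units x (8 directions x 250 ms) matrix of smoothed,
trial-averaged, rotated firing-rate modulation (rows mean-centered over all
2000 columns and normalized to unit range), `E` is the matching 2 x 2000
eye-velocity matrix shifted forward by the 25-ms behavioral lag, and `W`
(2 x units) is fit by ridge regression. Preparatory activity is then
projected through the same weights,

  PE = W N_1D,

where `N_1D` holds the fixation-period averages (first 150 ms and last
50 ms discarded, each row zeroed at its first retained sample and scaled by
the same ranges as `N_8D`). Predicted speed is the vector norm of `PE` and
predicted direction its two-argument arctangent. A single-trial variant
samples one fixation-duration-matched trial per unit (100-ms duration
bins), pushes the per-trial preparatory modulations through `W`, and
repeats 1000 times to give bootstrap distributions of predicted direction
and speed.

Pseudo-population assembly follows the experimental logic: each unit's
tuning is rotated so its single-direction block lies at 0 degrees, eye
velocity is rotated by the same angle (speed-preserving), and every
(unit, single-direction block) pair contributes one row.

### Ridge penalty

The penalty is chosen by generalized cross-validation over a logarithmic
grid `10^-4 ... 10^2` (in units of the mean squared singular value), with
one correction: the traces entering the fit are Gaussian-smoothed with
sigma = 20 ms, so neighboring milliseconds are not independent samples.
GCV therefore counts `T / (2 sqrt(pi) sigma)` effective samples rather
than `T`. Without this correction GCV treats the 2000 smoothed columns as
independent and under-penalizes badly: on synthetic data with rate noise
at 10% of the pursuit amplitude, the planted weights are recovered to
about 4% relative error with the correction and to only ~45% without it.
A fixed-lambda override is available, and `lambda = 0` requests the exact
ridgeless solution (an error if the rate matrix is rank deficient). The
behavioral lag defaults to 25 ms with 0 and 50 ms as documented
alternates.

## Subspace geometry and the loading-ratio decomposition

Preparatory (`N_prep`, units x 1400 ms) and pursuit (`N_purs`, units x
750 ms: 125 ms per speed-contrast condition) matrices are analyzed by PCA
after normalizing each row to unit range and centering it on its mean.
The angle between the first components of the two epochs,

  theta = arccos( PC_Prep1 . PC_Purs1 / (|PC_Prep1| |PC_Purs1|) ),

measures reorganization between preparation and action: 0 means the same
population pattern serves both epochs, 90 means complete reorganization.
Because an angle needs oriented vectors, each epoch's first component is
oriented so that the projection of the population activity onto it is
nonnegative at the epoch's final sample; obtuse angles are therefore
meaningful and are not folded back below 90.

The bootstrap draws 20 units without replacement from each of the eight
relative-direction bins (a balanced 160-unit pseudo-population), computes
both first components and their angle per iteration, and repeats 1000
times; it reports the mean angle, the percentile 95% interval, and
two-sided bootstrap p-values against 0 and 90 degrees. Per-unit loading
ratios `PC_Prep1 / PC_Purs1` are averaged over the iterations in which a
unit was sampled (a ratio is flagged undefined when the pursuit loading is
below `1e-3` of its root-mean-square). The ratio distribution is tested
for bimodality with Hartigan's dip test, and the sign of the mean ratio
splits units into subpopulation 1 (positive: same pattern in preparation
and pursuit) and subpopulation 2 (non-positive: pattern reverses). The
subpopulation comparison reports per-group bootstrap angles, the Spearman
correlation between preparatory and pursuit modulation, normalized
preparatory modulation by relative-direction class (same / orthogonal /
opposite, with half-open 45-degree boundaries: a difference of exactly 45
is orthogonal), and a readout model refit on each subpopulation alone.

## Demixed PCA

For units observed with single-direction blocks both toward and away from
their preferred direction, the mean-centered preparatory matrix `X`
(units x 2 conditions x 1400 ms) is decomposed into a condition-average
("time", direction-independent) marginalization and a per-condition
residual ("direction") marginalization; the two parts plus the noise
residual reconstruct `X` exactly. For each marginalization an
encoder-decoder pair minimizing `||X_phi - F D X||^2` is found by
reduced-rank regression: the least-squares map is projected onto its
leading singular subspace. Components are pooled across marginalizations
and ordered by explained variance; because the marginalizations are
orthogonal, each component's variance splits exactly into
direction-independent and direction-dependent shares. With trial-averaged
input the regression uses the minimum-norm (pseudoinverse) solution at
zero regularization -- the matrices involved are low rank by construction,
and an optional ridge term is exposed for noisy designs. Ten components
are kept by default; only one categorical factor is supported.

## Pulse-probe behavioral gain

Visual-motor gain is probed behaviorally by a 5 deg/s, 50 ms pulse of
target speed delivered 550-1350 ms after fixation onset. Trials whose
response window (pulse onset to 200 ms after it) intersects a detected
saccade are discarded; saccades are maximal intervals where eye speed
exceeds 30 deg/s or central-difference acceleration exceeds 1000 deg/s^2
(strict inequalities, thresholds configurable, intervals padded by 10 ms).
The response is the maximum eye speed in the 200 ms after pulse onset.
Gain dynamics are summarized by per-session ordinary-least-squares slopes
of response against pulse time (deg/s per s) separately per pulse
direction class, with display means over 200-ms bins reported at bin
centers; context effects (fast vs slow expected-speed blocks) use the
paired two-sided Wilcoxon signed-rank test with its normal-approximation
z, plus paired Cohen's d (mean over sd of the differences); and the link
to neural preparation is the per-neuron regression slope of behavioral
response on preparatory firing rate across matched fixation-time bins.

## Statistics

All tests used by the pipeline are implemented in the package so that the
reported quantities (z statistics with continuity correction, exact
enumeration, Monte-Carlo p-values) are available uniformly: Spearman rank
correlation (average ranks for ties; exact permutation p below n = 10, t
approximation otherwise), Wilcoxon signed-rank (exact enumeration over
sign assignments up to n = 12, normal approximation with tie and
continuity corrections beyond) and rank-sum tests, paired and pooled
Cohen's d, and percentile bootstrap intervals by linear interpolation of
order statistics. The base-R implementations serve as independent
cross-checks in the test suite.

Hartigan's dip statistic is computed exactly: the empirical cdf's step
corners define, for every candidate mode placement, upper and lower bands
that a nondecreasing convex-then-concave fit must thread; the minimal
band half-width follows from the greatest convex minorant of the left
corners and the least concave majorant of the right corners, and the dip
is the minimum over mode placements (between order statistics, or an atom
at one, which is what matters for heavily tied samples). The test's
p-value is Monte-Carlo against the uniform null (1000 simulations by
default, add-one convention), which keeps the procedure self-contained
and exactly seeded. The implementation is validated in the test suite
against an independent linear-programming oracle on small samples.

## The synthetic-data generator

The generator is the package's ground-truth supplier, emulating the
experimental design the analyses assume: interleaved 8-direction pursuit
blocks at 15 deg/s; single-direction blocks whose speed blend follows the
block context (fast: 80% at 20 deg/s, 20% at 10; slow: 80% at 2; control:
10 only; and a "mixed" design simplification covering 2/10/20 deg/s at
both 12% and 100% contrast so a single block supports the speed/contrast
cross-validation); fixation durations uniform on 800-1600 ms; and
pulse-probe sessions. Its main planted structures:

* **Pursuit tuning.** Zero-mean von Mises direction tuning (peak
  normalized, negative away from the preferred direction) with
  contrast-dependent latency (60 ms at high, 90 ms at low contrast).
  Units carry fixed heterogeneity -- tuning width, latency, rise time,
  and a latency-locked transient component of varying amplitude, center
  and width -- emulating the transient/sustained diversity of real
  pursuit neurons. This heterogeneity is load-bearing: it is what makes
  the 8-direction rate matrix full row rank, so the planted readout is
  identifiable at zero ridge.
* **Preparatory ramps.** Linear ramps from 150 ms after fixation onset
  (unit amplitude at 1400 ms), frozen at motion onset. Subpopulation 1
  ramps with amplitude `prep_amp_1 * cos(delta)` (delta = block direction
  relative to preferred); subpopulation 2 with
  `prep_amp_2 * max(0, -cos(delta)) + c`, positive for orthogonal and
  opposite blocks and near zero for same-direction blocks. The offset c
  defaults to `prep_amp_2 / 4` so orthogonal preparation is positive; the
  functional form is a declared modeling choice recorded in the planted
  truth.
* **The planted readout.** Column i of `W_true` is
  `readout_scale * (cos, sin)(relative preferred direction) / n`, the
  cosine rule in the frame the pseudo-population is assembled in. Eye
  velocity in the pursuit epoch is `W_true` applied to the smoothed,
  mean-centered, range-normalized population rate delayed by 25 ms, plus
  behavioral noise scaled to the rate noise. Defining the planted readout
  on the processed representation (rather than on raw rates) is what
  makes noise-free recovery exact and therefore testable; a consequence
  is that synthetic pursuit-epoch eye traces carry a small preparatory
  leak that real, gain-gated eyes would not show. Fixation-epoch eye
  velocity is zero.
* **Planted subspace geometry.** With a target angle requested, the
  preparatory ramp signs are flipped for a fraction
  `(1 - cos(theta)) / 2` of rows relative to their pursuit signs,
  allocated across relative-direction bins by largest remainder so the
  planted angle is a population-geometry property rather than a
  direction confound. The planted loading vectors and the realized angle
  (computed by the same arccos formula the analysis uses) are stored in
  the ground truth.
* **Planted gain.** Pulse responses peak at
  `5 * context_factor * G(t, delta)` with
  `G = g0 + a_dir cos(delta) + (b0 + b1 cos(delta)) t` (t in seconds from
  fixation onset), as a raised-cosine transient peaking 100 ms after
  pulse onset. Defaults (`g0 = 0.3`, `a_dir = 0.09`, `b0 = 0.145`,
  `b1 = 0.065`; context factors 1.025 / 0.77 / 1.0) put the
  same-direction slope at 1.05 deg/s per s, the orthogonal slope at
  0.725, and the fast/slow mean responses at 3.02 and 2.27 deg/s --
  the regime the analyses are meant to operate in. Session-level and
  context-block-level multiplicative gain scatter (relative sds 0.12 and
  0.17, sized from the across-session dispersion such experiments show,
  so paired context effect sizes land near 1 instead of the implausibly
  large values a variability-free world would give) applies whenever rate
  noise is on and is switched off with it, keeping noise-free datasets
  exactly deterministic. A configurable
  fraction of pulse trials carries an inserted 200 deg/s, 30 ms saccade
  transient for rejection testing.

Noise is Gaussian on the underlying rate per 1-ms bin (the analyses all
operate on smoothed trial averages, so Poisson spiking would add cost
without changing what is tested); `noise_sd = 0` makes the entire dataset
deterministic and every estimator exact. Identical seeds give
bit-identical datasets.

What the generator does not emulate: context-dependent preparatory
amplitude (fast vs slow blocks share one ramp), saccade kinematics beyond
the inserted transients, Poisson spike-count variability (available
conceptually but not the default), and any trial-history structure.
Passing recovery tests on this synthetic world therefore shows the
estimators are correct and calibrated under the stated model, not that
real recordings satisfy the model.

## Numerical choices and degenerate inputs

* Trial averages aligned to fixation contribute each trial only up to its
  own motion onset; samples beyond the longest fixation hold the last
  observed average. Smoothing uses a unit-mass Gaussian kernel truncated
  at 4 sigma with edge renormalization, so constants pass unchanged.
* Preferred directions are weighted circular means of rectified,
  baseline-subtracted pursuit responses; a near-zero resultant flags the
  direction undefined and the unit unclassified.
* Rows of `N_8D` whose range falls below `1e-6` of the population median
  are excluded (with the reason recorded); rows that are flat in a PCA
  input are kept at zero loading rather than amplified.
* Ties at the 45/135-degree class boundaries go to the farther class
  (half-open intervals); a loading ratio of exactly zero is
  subpopulation 2.
* Bootstrap seeds are explicit everywhere; child seeds are derived from
  one master seed by a fixed linear-congruential step, and all stay below
  2^31.

## Study sizes

The bundled analysis scripts and acceptance checks run at sizes chosen to
exercise the statistics faithfully at desk scale: populations of 160-192
units (balanced bins of 20-24, matching the bootstrap's 20-per-bin draw
against a smallest real bin of about 24), 4 trials per condition (the
inclusion floor used for real units), 1000 bootstrap iterations
throughout, 30 direction-experiment and 26 context-experiment pulse
sessions, and 10 generation replicates per planted angle in the
angle-recovery study. Heavier configurations are a matter of changing
`synthetic_config()` arguments.

## Known limitations

* The pseudo-population treats multiple single-direction blocks of one
  neuron as independent rows, exactly as the analyses it reimplements do;
  the generator's default gives each unit one block, so this assumption
  is untested here.
* The without-replacement, finite-population bootstrap understates
  estimator variance when bins barely exceed the group size; with the
  default bins of 24 drawing 20, interval coverage is adequate (checked
  in the acceptance suite) but would degrade if bins shrink toward 20.
* The dip test's Monte-Carlo null is the uniform distribution, the
  standard calibration for unimodality testing; p-values for strongly
  non-uniform unimodal nulls are conservative.
* `read_dataset()` accepts the package's own plain-text container and
  simple per-unit modulation tables with explicit column maps; loaders
  for external source-data files must be adapted to their actual layout.
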