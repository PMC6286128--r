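---
title: "Attentional gain fields and population receptive fields: the model behind attnprf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentional gain fields and population receptive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

A voxel's population receptive field (pRF) is the region of visual space
that drives its BOLD response, modelled here as an isotropic 2D Gaussian
with center $(x, y)$, size $\sigma$ (all in degrees of visual angle, dva),
a response amplitude and a baseline. When covert spatial attention is
directed to a location, measured pRFs shift; `attnprf` implements the
multiplicative gain-field account of this resampling: the measured pRF is
the pointwise product of a *stimulus drive* (SD, the pRF outside
attentional influence) with a Gaussian *attentional gain field* (AF)
centered at the attended location. Because a product of Gaussians is
Gaussian, with precisions adding and the center at the precision-weighted
mean, a narrower AF pulls the measured pRF further toward the attended
location, and narrower SDs shift less.

Three task conditions are modelled. Under **Attend Fixation** attention
sits at the origin, so the measured pRF is `gaussian_product(SD, AF_fix)`
in closed form. Under **Attend Color** and **Attend TF** (temporal
frequency) attention follows a traversing bar stimulus, so the locus of
attention changes with time. Following the model, each unique bar mask is
convolved with the stimulus AF kernel and multiplied with the SD; each
product is scaled to a maximum of 1 and the products are averaged over the
unique bar stimuli. The peak of this averaged ("smeared") profile is the
predicted attend-stimulus pRF position. **Attend Stimulus** denotes the
per-parameter average of the two attend-bar conditions.

Inverting the model (`fit_af_sizes`) estimates the two AF sizes from
measured pRFs by grid search: for each candidate (fixation AF size,
stimulus AF kernel size) the SD of each input is recovered by Gaussian
*division* of its Attend Fixation pRF, the attend-stimulus position is
predicted, and the summed squared distance to the measured positions —
aggregated into an 8 x 8 grid of visual-field bins over the mirrored
quadrant — is minimized. Reported stimulus AF sizes add the bar width
(0.9 dva) to the kernel size, the effective size of a kernel convolved
with the bar.

## Stimulus design and forward model

The mapping stimulus is a bar of width 0.9 dva traversing a circular
aperture of radius 3.6 dva in 8 directions, stepping 0.34 dva every
1.6 s (one TR), 24 positions per pass, 24 passes per run (3 per
direction, seeded random order), a 4.8 s pause after each pass and four
38.4 s blanks, one after every sixth pass — 744 frames, 1190.4 s. Bar
frames are rasterized on a square grid (extent 7.2 dva; 31 x 31 for the
coarse stage, 101 x 101 for the fine stage) as binary strips: a pixel is
on when its center lies within half a bar width of the bar center line,
clipped to the aperture. The traversal spans aperture diameter plus bar
width symmetrically, so first/last frames are partially clipped; where
the original design leaves placement of pauses and blanks open, the
package fixes them as above and exposes them as configuration.

Neural time courses are mapped to BOLD by causal convolution with a
double-gamma HRF (peak 6 s, undershoot 16 s, dispersions 1 s, peak:
undershoot 6, length 32 s, unit sum). A parametric HRF shared between
simulator and fitter replaces per-subject HRF estimation, which needs a
separate experiment and is out of scope.

## The synthetic-data generator

`sample_ground_truth_voxels()` draws SD centers uniformly over the
stimulated disk (eccentricity 0-3.3 dva) with sizes following a linear
size-eccentricity relation (intercept 0.25 dva, slope 0.2, Gaussian
jitter 0.05 dva) — values typical of early visual cortex. An optional
axial von Mises bias (`polar_angle_kappa`) over-represents the horizontal
meridian, a documented property of visual-cortex coverage; it is off by
default and switched on where an analysis depends on that property (the
radial-vs-horizontal-vs-vertical shift ordering only emerges given
non-uniform coverage, which is also how the original analysis explains
it). Feature preference decreases linearly with eccentricity (color
preferred foveally).

`generate_bold_timeseries()` produces condition data from the generative
model. For the attend-bar conditions three variants are available:

* `"gaussian"` (default): a static Gaussian effective pRF at the
  position the model predicts (the argmax of the averaged product
  profile), sized as the product of the SD with the effective stimulus
  AF. Fitted pRFs then recover exactly the position the inversion
  predicts, making forward/inverse consistency testable.
* `"smeared"`: the averaged product profile itself. It is skewed toward
  the fovea, so a Gaussian fit lands systematically short of its peak —
  useful for studying that bias, but not self-consistent with the
  position-only inversion.
* `"traveling"`: the frame-wise products drive each frame's response
  directly. Measured during development: this produces essentially *no*
  shift in fitted centers (the per-frame responses remain centered on
  the SD; only the equal per-frame weighting of the averaged profile
  produces the pull), so it is kept as an ablation, not the default.

Noise is i.i.d. Gaussian per sample at a fraction of the amplitude (20%
default), with an AR(1) option. `n_runs` (default 2) averages independent
repetitions of the traversal sequence per condition, emulating a session
of several mapping runs (the study design acquires 6-8 runs with one
pass per condition and direction each, i.e. 48-64 passes per condition;
two full sequences equal the lower end). For identical regressors the
run average is the exact least-squares equivalent of concatenation.

The generative AF defaults are `sigma_fix = 2.5`, `sigma_stim_color =
0.65`, `sigma_stim_tf = 0.75` dva. They lie inside the model's search
ranges and were chosen once so that the generator emulates the study's
qualitative findings: a ~0.1 dva more precise stimulus AF when color is
attended, and an eccentricity-change profile (Attend Stimulus minus
Attend Fixation) that is positive parafoveally and negative peripherally.
What passing tests show is that the pipeline recovers the structure this
generator built in; real data add non-Gaussian pRFs, structured
(physiological and motion) noise, HRF variability and voxel correlations
that the generator does not emulate.

## pRF estimation

Fitting follows a three-step procedure. (1) `ridge_init()`: L2-penalized
regression ($\lambda = 10^6$) of the z-scored, concatenated condition
time series on the HRF-convolved 31 x 31 pixel regressors; the
coefficient peak initializes the center (ties break to the lowest
flattened pixel index). (2) `fit_prf_joint()`: one Gaussian (x, y,
sigma, amplitude, baseline) fit to all conditions on the 101 x 101
design. (3) `fit_prf_per_condition()`: per-condition Gaussians with one
shared baseline (13 free parameters), initialized at the joint fit.
$R^2 = 1 - \sum_i (m_i - p_i)^2 / \sum_i (m_i - \bar m)^2$ is computed on
the concatenated prediction; `select_voxels()` discards voxels with
Attend Fixation eccentricity above 3.3 dva, size above 7.2 dva in any
condition, or $R^2 < 0.1$.

Numerical choices: the objective is smooth nonlinear least squares, so
the package uses Levenberg-Marquardt (`minpack.lm::nls.lm`) with analytic
Jacobians and native box bounds (center within ±5 dva, size in
[0.05, 10] dva) rather than a derivative-free search; the size is
initialized at the best of {0.25, 0.5, 1, 2} dva by linear-subproblem
SSE. Predictions exploit linearity: `conv(masks %*% g)` equals
`W %*% g` for the dense convolved design `W` but costs one sparse
product. Non-convergence is flagged on the record, never raised; flagged
voxels leave analyses through the $R^2$ filter. Fitted parameters are
clamped to the bounds on output.

## Gain-field inversion

The grid search evaluates 50 evenly spaced values per dimension
(fixation AF 1.5-2.5 dva, stimulus kernel 0.6-1.6 dva), start-anchored
with spacing range/50 = 0.02 dva (an endpoint-inclusive option exists).
Ties break toward the smaller fixation size, then the smaller kernel.
Inputs with measured size not smaller than the candidate fixation AF are
non-invertible and excluded from that cell; a cell with no usable input
scores infinity.

Two objective modes exist because "predict per binned vector" and "bin
the per-voxel predictions" differ through the nonlinear division and
argmax:

* `predict_per = "bin"` derives one SD per binned vector from the
  bin-averaged Attend Fixation pRF. It is exactly self-consistent when
  the forward data are themselves binned vectors.
* `predict_per = "voxel"` derives SDs and predictions per voxel and
  aggregates predictions with the same R^2-weighted binning as the
  measured positions. It is exactly self-consistent for voxel-level
  forward simulations and is the mode used for voxel-level recovery
  studies; with bin-mode applied to voxel-level data the objective's
  shallow diagonal valley (larger fixation AF trades off against a
  larger kernel) converts the aggregation mismatch into a kernel bias of
  several grid steps.

The 96 geometrically unique bar masks (opposite traversal directions
yield identical masks) carry weight 2 each, which is identical to
averaging over all 192 unique bar stimuli.

## Descriptive statistics

Positions are mirrored into the first quadrant with the sign of the
Attend Fixation coordinates (zero counts positive), preserving
cross-meridian shifts. Shift decomposition reports R^2-weighted mean
ratios |Δecc|/L, |Δx|/L, |Δy|/L; the polar-angle analysis bins the
quadrant angle into three bins with 0 at the *horizontal* meridian (some
retinotopy conventions run the axis the other way, which flips every
slope sign), so the first-vs-last-bin contrast
`(Δx_last − Δx_first) − (Δy_last − Δy_first)` is *positive* for
radial, net-inward shift fields and negative for net-outward ones. Eccentricity/size changes are profiled over four
equal-width Attend Fixation eccentricity bins (equal-count optional) and
correlated over twenty 5-percentile bins with a Fisher-transform CI;
outliers beyond five unscaled median absolute deviations are rejected
per bin, and a zero MAD excludes nothing (with a warning). The feature
attention modulation index normalizes per-condition (Δecc, Δsize)
vectors by the across-voxel *standard deviation* of the Attend
Stimulus − Attend Fixation differences — the SD keeps the two components
commensurate and dimensionless; `norm = "variance"` reproduces the
literal reading. Inference uses a voxel bootstrap (weights inside the
statistic, not in the resampling probabilities), two-tailed p as twice
the smaller tail fraction floored at 2/n_boot, Benjamini-Hochberg FDR,
and the small-sample-corrected Rayleigh test.

## Behavioural and gaze modules

`simulate_staircase_observer()` is a Bayesian one-parameter staircase on
a log-intensity lattice (Gaussian prior, Weibull likelihood with slope
3.5, guess 0.5, lapse 0.02) placing each trial at the posterior-mode
threshold plus the fixed offset that maps to 83% correct; a matched
Weibull observer then converges to that accuracy. `clean_gaze()`
interpolates blink gaps linearly, high-pass filters the pupil at 10 Hz
*for detection only*, invalidates samples whose filtered-pupil
acceleration exceeds 1e5 units/s^2 together with neighbors within 5 s,
and (given the bar sequence) removes per-pass drift by median
subtraction. Gaze is summarized per bar position as the across-pass
median and SD of the along-traversal component.

## Problem sizes used by the test suite

The suites run at desk scale, chosen as the smallest sizes that
exercise each claim: 100 voxels for noisy parameter recovery, 250 voxels
for the noisy gain-field recovery (dense 8 x 8 quadrant coverage), 500
voxels for population-level direction effects, 300-600 model-level
populations for geometry checks, 10^3-10^4 bootstrap resamples in tests
(10^5 is the analysis default), and 2 runs per condition (the study's
lower bound of acquired data).

## Known limitations

* The model predicts positions only; amplitude and size changes are not
  part of the inversion objective.
* Isotropic Gaussians throughout: no surround suppression, no
  compressive spatial summation.
* The per-voxel inversion inherits noise through a convex
  division/argmax chain, so recovered AF sizes scatter along the
  objective's shallow valley; population size and run count control this
  variance.
* The simulated observer shares the staircase's psychometric family;
  model mismatch between observer and staircase is not explored.
* Grid quantization (0.071 dva pixels at 101 x 101) bounds the precision
  of predicted positions; near-foveal predicted shifts are dominated by
  it.
* For a *static* gain field the Gaussian-multiplication property holds:
  a smaller field always pulls harder. The traveling-average prediction
  is non-monotone in the stimulus kernel size — within the search range
  a wider kernel can pull peripheral stimulus drives further inward
  (measured pull at 3.25 dva eccentricity: 0.40 dva at kernel 0.6, 0.61
  at 1.2), and the pull vanishes in the flat-gain limit. Intuition about
  "narrower = stronger" transfers only locally.
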