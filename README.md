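# attnprf

Population receptive field (pRF) mapping under spatial and feature-based
attention, as a fully simulated and testable R pipeline.

## What it is for

In visual cortex, a voxel's pRF — modelled as an isotropic 2D Gaussian
with center $(x, y)$, size $\sigma$ (degrees of visual angle, dva) — is
not fixed: directing attention to a location pulls measured pRFs around.
The multiplicative *attentional gain field* (AF) model explains this
resampling: the measured pRF is the pointwise product of a stimulus-drive
Gaussian $SD$ (the pRF outside attentional influence) with a Gaussian
gain field $AF$ at the attended location,

$$\mathrm{pRF} = SD \cdot AF, \qquad
  \frac{1}{\sigma^2} = \frac{1}{\sigma_{SD}^2} + \frac{1}{\sigma_{AF}^2},
  \qquad
  \mu = \frac{\mu_{SD}/\sigma_{SD}^2 + \mu_{AF}/\sigma_{AF}^2}
             {1/\sigma_{SD}^2 + 1/\sigma_{AF}^2}.$$

During mapping with a traversing bar, attention to the bar moves with it;
the model handles this by convolving each unique bar stimulus $dm(t)$
with a stimulus gain-field kernel $AF_{stim}$, multiplying with the SD,
scaling each product to a maximum of 1, averaging over bar stimuli, and
taking the argmax of the average as the predicted attend-stimulus pRF
position:

$$\mathrm{pRF}_{stim}^{pos} = \arg\max \frac{1}{n}\sum_{t}
  \frac{(dm(t) * AF_{stim}) \cdot (\mathrm{pRF}_{fix} / AF_{fix})}
       {\max\left[(dm(t) * AF_{stim}) \cdot (\mathrm{pRF}_{fix} / AF_{fix})\right]},$$

where $\mathrm{pRF}_{fix} / AF_{fix}$ is the SD recovered by Gaussian
*division* of the measured Attend Fixation pRF. Inverting the model fits
the two gain-field sizes on a 50 x 50 grid (fixation AF 1.5–2.5 dva,
stimulus kernel 0.6–1.6 dva, 0.02 dva precision) by minimizing the L2
distance between predicted and measured attend-stimulus positions over
up to 64 quadrant-binned shift vectors.

The package is aimed at visual neuroscientists who want to simulate,
fit, and invert this model end to end: a bar-stimulus design and
double-gamma HRF forward model, a generative simulator of
condition-specific BOLD (Attend Fixation / Attend Color / Attend TF), the
three-step pRF estimation (ridge back-projection, joint Gaussian fit,
per-condition refit with a shared baseline), voxel selection, the
gain-field grid inversion, shift-direction and eccentricity/size-change
analyses, the feature attention modulation index (AMI), an adaptive
staircase behavioural simulator, gaze cleaning, and weighted-bootstrap /
FDR / Rayleigh statistics. Everything is verifiable by parameter
recovery on synthetic data; no external data are required.

## Worked example

```r
library(attnprf)

seq   <- build_bar_sequence()                 # 24 passes, 744 frames
hrf   <- hrf_double_gamma(dt_s = seq$dwell_s)
dm101 <- render_design_matrix(seq, 101)
dm31  <- render_design_matrix(seq, 31)
reg101 <- convolve_design(dm101, hrf)
reg31  <- convolve_design(dm31, hrf)

af <- af_spec()          # generative gain fields: 2.5 / 0.65 / 0.75 dva
ds <- simulate_prf_dataset(60, dm101, hrf, af, noise_frac = 0.2, seed = 1)
fits <- fit_prf_dataset(ds, reg31, reg101)
sel  <- select_voxels(fits)

recs <- shift_records(sel$fits, "AttendStimulus")
decompose_shift_directions(recs[recs$L > 0, ], n_boot = 2000, seed = 1)$ratios
#>   component estimate ci_low ci_high
#> 1       ecc    0.772  0.700   0.842
#> 2         x    0.648  0.565   0.725
#> 3         y    0.614  0.534   0.694

fit_af_sizes(recs, dm101, predict_per = "voxel")
#> gainfield_fit: sigma_fix = 2.440 dva, stimulus kernel = 0.740 dva (effective 1.640 dva)
#>   objective 0.09187 over 32 vectors

ami <- compute_feature_ami(sel$fits)
weighted_bootstrap(ami$feature_ami[ami$defined], ami$w[ami$defined],
                   n_boot = 10000, seed = 2)
#> bootstrap: estimate 0.1401, 95% CI [0.06649, 0.2089], p < 2e-04 (n_boot 10000)

simulate_staircase_observer(seed = 1)
#> staircase_sim: 1000 trials, target 83%, accuracy last half 82.6%, threshold estimate 0.300
```

Reading the numbers: shifts are predominantly radial (the eccentricity
ratio 0.77 exceeds the horizontal 0.65 and vertical 0.61 ratios); the
grid inversion recovers gain-field sizes close to the generative values
(2.5 dva fixation, ~0.70 dva mean stimulus kernel) from just 60 noisy
voxels; the positive feature AMI (0.14, p < 2e-4) reflects the smaller —
more precise — color gain field in the generator; and the staircase
holds a matched 2AFC observer near its 83%-correct target.

A staged pipeline with TSV/JSON artifacts and manifests is available as
`run_pipeline()` (configuration via `default_config()` / YAML), plus a
shell wrapper in `inst/scripts/attnprf.R`.

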