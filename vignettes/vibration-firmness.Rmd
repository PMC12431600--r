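---
title: "Image-based vibration analysis for fruit firmness: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based vibration analysis for fruit firmness: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibrofruit)
```

## The measurement problem

Fruit firmness is the standard ripeness proxy in postharvest handling, but
the penetrometer that measures it destroys the fruit. A vision-only
alternative excites the fruit with a small vibration motor, films the
vibrating surface with a high-speed camera (1000 frames per second over a
20 s record), and reads two mechanical features off the displacement of
the surface centre:

* the **natural frequency** `f_n` (Hz), the location of the dominant peak
  of the FFT magnitude spectrum, searched in the 200–300 Hz excitation
  band — stiffer tissue vibrates faster;
* the **damping ratio** `ξ` (dimensionless), estimated by the
  *logarithmic decrement*
  `ξ = ln(x_i / x_{i+j}) / (2πj)`
  from oscillation peaks `x_i` and `x_{i+j}` spaced `j` cycles apart —
  softer, more viscoelastic tissue dissipates energy faster.

A small feed-forward network `q = f(Σ w_i p_i + b)` with two inputs
(`ξ`, `f_n`), one tanh hidden layer and a linear output maps the feature
pair to firmness in MPa. This package implements the whole chain —
signal/frame simulation, sub-pixel tracking, modal feature extraction,
network training and evaluation — so that every stage can be validated
against known ground truth without access to a physical rig.

## The synthetic cohort: what it emulates

No public dataset of vibrating-fruit recordings exists, so the package
ships a first-class simulator. Its defaults encode the study conditions
the pipeline is meant to reproduce: a cohort of 120 Hayward kiwifruit
spread over four ripening stages, whose firmness, natural frequency and
damping ratio follow stage-level distributions with these anchors:

```{r}
stage_parameters()
```

`sample_stage_parameters()` draws each quantity from a truncated normal
with the stage mean and SD (damping truncated to (0, 1), the rest to the
positive reals). Note that the overripe damping mean 0.957 sits only about
one SD below the upper bound, so the *expected* draw is visibly below the
nominal mean — the tests compare Monte-Carlo means against the closed-form
truncated-normal mean, not the nominal one.

`generate_cohort()` adds one design decision the stage table cannot
provide: within a stage, softer individuals should vibrate at lower
frequency with higher damping, otherwise the features carry no
within-stage information about firmness. We couple the three draws with a
Gaussian copula (default correlation 0.9 with frequency, −0.9 with
damping) while keeping the stage marginals exactly as tabulated. A
firmness-propagation alternative (mapping each fruit's firmness through
the piecewise-linear `firmness_to_modal()` interpolant) was rejected
because the map slope (~7 Hz per MPa) would inflate the within-stage
frequency spread to several Hz, contradicting the tabulated SDs of 0.9 to
1.9 Hz. With `sd_scale = 0` the cohort degenerates to the four stage-mean
triples, which many tests exploit.

What the simulator deliberately does **not** model: fruit shape asymmetry,
skin texture, lighting, rolling shutter, motion blur, multi-modal
vibration, or any effect of mass and diameter on the modal parameters
(both are recorded but unused). Passing tests therefore demonstrate the
*algorithmic* fidelity of the pipeline, not robustness to every nuisance
of real footage.

## Signal model and the two envelope conventions

`generate_displacement()` produces a forced steady sinusoid at the fruit's
own natural frequency (resonant excitation, the default 18 s) followed by
free decay (2 s), phase-continuous at the switch, because the logarithmic
decrement is only defined on free decay while the spectral peak is
sharpest during forced excitation. The switch time is recorded on the
trace; `extract_modal_features()` uses it, or falls back to a rolling-RMS
detector (decay starts after the last sample whose rolling RMS reaches
90 % of the plateau value).

Two decay envelopes are available:

* `log-decrement-consistent` (default):
  `A·exp(−2π ξ f_n t)·cos(2π f_n t)`. Successive displacement peaks are
  exactly one period apart with ratio `exp(2πξ)`, so the printed
  decrement formula recovers the generating `ξ` exactly — the convention
  used by all round-trip tests.
* `physical-sdof`: `A·exp(−ξ ω_n t)·cos(ω_d t)` with
  `ω_d = ω_n√(1−ξ²)`. Here the per-cycle decrement is
  `2πξ/√(1−ξ²)`, so the small-damping formula overestimates `ξ` and the
  exact conversion `ξ = δ/√(4π² + δ²)` (available as
  `method = "exact-sdof"` in `damping_log_decrement()`) recovers it. The
  small-damping form stays the default because it is the formula the
  measurement protocol prescribes.

## Numerical choices in the modal module

**Sampling rates.** The camera rate of 1000 samples/s gives only ~3.7
samples per cycle at 272 Hz — ample for the FFT peak, far too coarse for
peak-amplitude interpolation. Frequency round-trips therefore run at
1000 Hz and damping round-trips on 10 kHz free decays. This is a
property of the decrement method itself: at the camera rate, damping
estimates from these frequencies are semi-quantitative.

**Spectrum.** The magnitude spectrum is computed from the mean-removed,
linearly detrended trace, zero-padded to the requested grid. The
reporting grid is 1 Hz; feature extraction defaults to a 0.05 Hz
zero-padded grid, which a 20 s record supports natively
(20 000 samples at 1000 Hz). No window is applied by default; the forced
tone dominates the record. Ties in the band search resolve to the lower
frequency. Both the 200–300 Hz band-argmax (default) and a
first-local-maximum mode are provided, since either convention appears in
practice.

**Peak picking.** Interior positive local maxima, refined by three-point
parabolic interpolation of time and amplitude. Two guards matter for
strongly damped decays, where the second interior peak is already
~2.4·10⁻³ of the envelope and the third ~6·10⁻⁶:

* peaks below `min_peak_ratio = 1e-3` of the largest peak are dropped, so
  the overripe estimate uses exactly the first two usable peaks;
* no linear detrend is applied before peak picking (`detrend = FALSE`): a
  least-squares line fitted to a one-sided decay has an offset of order
  10⁻⁴ of the envelope near `t = 0`, which is a several-percent error on
  those small late peaks. `extract_modal_features()` removes a *median*
  baseline instead, which is unbiased for an oscillation about an offset
  and numerically negligible otherwise. Detrending before the FFT, where
  it belongs, is always applied.

The decrement estimator averages over all valid successive pairs at a
fixed cycle gap (default `j = 1`); each term is the printed formula, so
the average is still an unbiased combination of exact per-pair estimates
and is `j`-invariant on exact exponentials.

## Rendering and tracking

`render_frames()` draws the fruit as an anti-aliased ellipse (64×64 px,
semi-axes 20×16 px by default) with a darker central marker disc,
translated along the vibration axis; anti-aliasing is by regular
supersampling (default 8×8 subsamples per pixel), implemented in C++ so a
20 000-frame record renders in seconds. The bounding check guarantees the
fruit never leaves the frame.

`track_displacement()` reproduces the measurement chain: Otsu threshold,
hole filling (the dark marker becomes a hole and is filled), largest
connected component, then the intensity-weighted centroid, projected on
the vibration axis relative to frame 0. Coordinates are continuous, with
the origin at the centre of pixel (0, 0), x rightward and y downward. One
subtlety: the binary mask cuts off faint anti-aliased edge pixels whose
fractional intensities carry most of the sub-pixel information, which
biases the weighted centroid by up to ~0.05 px. The tracker therefore
dilates the mask by one pixel before weighting (`mask_dilate = 1`); on a
dark background the restored pixels contribute exactly their fractional
weight, and the measured worst-case error on known rigid shifts drops to
~0.004 px. Segmentation itself is unchanged.

There is no drift correction or registration; slow drift is handled by
the detrending step in the modal module.

## Network and training

The predictor is the 2-H-1 network above with `H = 7` hidden units by
default, selected by 10-fold cross-validation over widths 1–20 elsewhere
in the workflow (an abstract-level description of the same study quotes
ten units; both are one `train_config()` argument away). Inputs and
target are z-scored on the training split only — damping lives in (0, 1)
and frequency near 250 Hz, and tanh units saturate without scaling.

Training minimises the sum of squares by Levenberg–Marquardt on the full
analytic Jacobian of the network: damping factor starting at 10⁻³,
×10 on step rejection, ÷10 on acceptance, stopping at gradient norm
< 10⁻⁸ or 1000 iterations, with 5 seeded uniform restarts keeping the
weights with the lowest prediction error (validation error when a
validation set is supplied, training error otherwise). All constants are
exposed in `train_config()`. The implementation is cross-checked in the
test suite against an independent MINPACK optimiser on the same
objective. Cross-validation folds are contiguous blocks after one seeded
shuffle; ties in the width selection resolve to the smaller width
(parsimony). The 70/30 split takes `ceiling(0.7 n)` training rows, so a
120-fruit cohort splits 84/36 and the paired comparison on the test set
has 35 degrees of freedom.

## Evaluation and uncertainty

`regression_metrics()` reports `R² = 1 − SS_res/SS_tot`, RMSE, the OLS
slope of predicted on actual (the reverse regression is a flag), and the
mean residual (bias). `residual_diagnostics()` adds type-2 sample
skewness (the SPSS/SAS definition), the Shapiro–Wilk p-value and the
slope of |residual| on the prediction as a heteroscedasticity measure.
`paired_t()` is the standard paired test with `n − 1` degrees of freedom.

`bootstrap_intervals()` case-resamples the training rows, refits with a
caller-supplied procedure (each refit gets a derived seed
`base + replicate`), and takes per-observation percentile bounds across
the refitted models' predictions, using the usual `(B+1)α` order-statistic
convention. These are confidence intervals for the *model prediction*:
their spread reflects refit variability, not observation noise. Coverage
is therefore computed against a caller-supplied reference vector — the
calibration tests pass the known noise-free regression function of a
well-specified synthetic problem, where the nominal 95 % level is the
textbook guarantee, and observed mean coverage over 20 replicates lands
in the 90–99 % range. When the reference is noisy observations, coverage
depends on how refit spread compares with the noise level and is reported
as-is, not calibrated.

## Problem sizes used by the tests

The suite favours exact, fast configurations: full 20 s records at
1000 Hz for frequency recovery, 2 s free decays at 10 kHz for damping
recovery, one full 20 000-frame video round trip, cohorts of 120 (plus
one 4000-fruit Monte-Carlo check of the stage marginals), teacher–student
and cohort fits with 5 restarts, and bootstrap calibration at
`B = 500` with 20 replicates over an OLS fitter. The whole suite runs in
about a minute and a half on one core.

## Known limitations

* Damping estimation at the camera rate (1000 samples/s) is coarse for
  modes near 250 Hz; the decrement wants ≥ ~30 samples per cycle.
* The decrement assumes a single dominant decaying mode; multi-mode
  responses, half-power-bandwidth damping and phase-based features are
  out of scope.
* The renderer is a geometric scene, not a photometric one; tracking
  performance on real footage with texture, shading and occlusion is not
  claimed by these tests.
* Stage statistics anchor the simulator to four ripening stages of one
  cultivar; other fruit or excitation bands need new anchors
  (`stage_parameters()` documents the defaults).
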