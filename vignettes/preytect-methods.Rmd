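---
title: "Methods: models, parameters, and design choices in preytect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in preytect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preytect)
```

`preytect` analyses a tethered virtual-hunting experiment in larval
zebrafish: 18 visual stimuli (16 moving spots coded by four binary features
— direction, speed, size, contrast polarity — plus two whole-field
flashes), one per 32 s epoch, with 60 Hz binocular eye tracking and 1.8 Hz
two-photon calcium imaging (57 whole frames per epoch). This vignette
documents the models, the parameters that matter, the synthetic-data
generator that underpins the test suite, and the design choices made where
the design was genuinely open.

## The behavioural feature-compound model

Hunting responses (convergent saccades) per spot epoch are modelled as
Bernoulli with

$$\mathrm{logit}(R) = \beta_0 + \beta_1\,\mathrm{size} +
\beta_2\,\mathrm{polarity} + \beta_3\,\mathrm{speed \cdot size \cdot
polarity},$$

on the bit coding left-to-right = 1, fast = 1, large = 1, dark = 1. The
default coefficients in `behavior_params()` are −6.51, 1.33, 1.87, 0.90,
so odds ratios are `exp(β)` and the best stimulus (large, dark, fast)
reaches a response probability just above 8%. `fit_logistic_model()` is a
plain maximum-likelihood binomial GLM; confidence intervals are Wald
(profile-likelihood intervals were the alternative; Wald was chosen for
speed and because at the trial counts involved the likelihood is close to
quadratic).

**Stepwise selection.** `stepwise_select()` searches the 15 candidate
product terms (4 mains, 11 interactions up to fourth order) by
bidirectional stepwise moves scored with BIC on the per-trial binomial
likelihood, then reports the winner's cross-validated R² computed on the
16 per-stimulus response rates over random trial halvings. Two remarks on
why this combination:

* Scoring *selection* on rate-level cvR² alone is degenerate: the 16 rates
  are dominated by the four large∧dark stimuli, so a single `size:polarity`
  indicator explains nearly all rate variance and a greedy forward search
  stops before the main effects enter, even at very large n. The per-trial
  likelihood distinguishes the low-rate groups; the BIC penalty makes the
  selection consistent; and the bidirectional moves drop the redundant
  `size:polarity` term once `size` and `polarity` enter. On data simulated
  from the default model at 20,000 trials per stimulus the search returns
  exactly `{size, polarity, speed:size:polarity}`.
* The rate-level cvR² is still the *reported* fit quality, because the
  natural summary of behavioural tuning is the 16-point rate profile.
  Internally the search aggregates trials to the 16 stimulus cells before
  fitting — the binomial likelihood is identical up to a constant, and the
  search runs on 16-row fits.

## Saccade detection and kinematics

A convergent saccade is defined binocularly: nasal rotations of both eyes
with onsets within **150 ms** of one another; onset is the earlier eye's
velocity-threshold crossing, and a 1 s refractory period collapses bursts.
Velocity is a first difference of a 50 ms running mean. Two additional
gates reject fixation noise: smoothed nasal velocity ≥ 20 °/s and per-eye
nasal displacement ≥ 1° (200 ms pre/post window means).

These gate defaults are deliberately permissive. The empirical
vergence-change distribution has mean 19.03° and SD 9.3°, so its lower
quartile lies below ~13° of vergence change (≈6.5°/eye). A strict gate of
5°/eye — a value one might naively pick — would censor that quartile and
bias any amplitude statistic upward by almost +3° (a truncated-normal
argument: E[X | X > 13] ≈ 23° for X ~ N(19.03, 9.3)). With the 1°/eye gate
the detection floor is ~2–3° of vergence change and amplitude statistics
are essentially unbiased, while false positives remain negligible because
the displacement windows average 12 samples each and both eyes must cross
both gates within 150 ms. All thresholds are configurable via
`saccade_params()`.

Kinematics use 200 ms pre/post windows; the post window starts 250 ms
after onset so that the slower eye's ramp (≤150 ms asynchrony plus ~100 ms
duration) has finished. Peak nasal velocity is the maximum smoothed
derivative within 400 ms of onset.

## The imaging front end

* **Registration**: per-frame rigid translation maximising FFT
  cross-correlation with the stack-mean template, parabolic sub-pixel
  refinement, shifts clipped at 20 px and flagged.
* **Segmentation**: seeds are local maxima of per-pixel temporal SD ×
  rectified local correlation (each pixel against its 4-neighbour mean),
  thresholded at max(median + 5·MAD, 25% of the map maximum); regions grow
  to soma-scale bounds (20–200 µm²) and oversized regions are split by
  2-means on pixel coordinates and flagged. This is a deliberately compact
  stand-in: it is validated on synthetic disk movies (20/20 somata, <2 µm
  centroid error), not on real tissue.
* **ΔF/F**: baseline F₀ is the mean of the first 3 frames of each epoch —
  valid because every stimulus starts ≥2 s (≥3.6 frames) into its epoch
  and the indicator decay (1.5 s) has died out by the next epoch start. A
  rolling-percentile baseline is available for recordings without an epoch
  structure.
* **Visual responsiveness**: for each of the 18 stimuli, a paired t-test
  of per-trial stimulus-window peak ΔF/F against per-trial baseline means,
  plus SNR = (max rep-averaged window signal − baseline mean)/baseline SD;
  a cell is responsive if any stimulus passes p < 0.05 **and** SNR > 3. No
  multiple-testing correction is applied across the 18 stimuli — the
  criterion is "modulated by at least one stimulus" — so the naive per-cell
  false-positive bound is 18α; in practice the SNR gate dominates and the
  measured false-positive fraction on pure-noise cells is below 5% (the
  test suite quantifies this). Negative-going (inhibited) cells are *not*
  captured by this peak-based gate; that is a known limitation.

## Tuning analysis

The **visual response vector** (VRV) concatenates the rep-averaged ΔF/F of
the first 38 frames of each epoch across the 18 stimuli in canonical order
(stimulus id = 8·direction + 4·speed + 2·size + polarity for spots, then
dim and bright flashes), giving 684 points; the clustering substrate is
the VRV divided by its SD.

**Clustering** is greedy seeded centroid clustering: the seed is the cell
with most neighbours at r ≥ 0.75; membership is grown/shrunk by
correlation to the centroid (mean member VRV) to a fixed point; members
are removed and the procedure repeats. Clusters must contain cells from at
least 6 fish. Retained members satisfy r ≥ 0.75 against their centroid by
construction — the tests assert this exactly. k-means and mixture-model
alternatives were considered out of scope.

**Selectivity indices** use SI = (R_pref − R_flip)/(R_pref + R_flip),
where R_pref is the largest rep-averaged peak ΔF/F over the 16 spots
(negatives rectified to 0 to avoid division pathologies) and R_flip is the
response to the same stimulus with the queried bit inverted; the sign is
oriented so positive means preference for bit value 1. The index is
undefined (NA) when both responses are zero.

## Non-linear mixed selectivity

Six binary regressors, all selective for large∧dark spots, optionally
adding speed and/or direction selectivity (ones counts 4, 2, 2, 1, 2, 1).
ROIs are assigned to the best-correlated regressor when r ≥ 0.75, ties
broken by fixed key order.

The model comparison fits, at **equal complexity** (5 parameters each):

* linear: `y ~ 1 + dir + speed + size + pol`
* non-linear: `y ~ 1 + size·pol + speed·size·pol + dir·size·pol +
  dir·speed·size·pol`

by least squares on per-trial peak responses (identity link: the responses
are continuous ΔF/F peaks). The first, second, and fourth interaction
terms define conjunction tuning with speed and direction refinements; the
third (`dir·size·pol`) was the one free choice — it carries
speed-independent direction selectivity and brings the parameter count to
parity. Cross-validation halves the repetitions of each stimulus
(`n_splits` = 20 by default), and
`SI_nlin = (cvR²_nlin − cvR²_lin)/(|cvR²_nlin| + |cvR²_lin|)` (0 when the
denominator is 0) is a bounded, symmetric summary of which model explains
held-out variance better; the specific functional form was an open choice.

**Receptive fields**: per responsive stimulus, the RF sample is the spot
azimuth one frame before the response peak, minus the mean
screen-coordinate gaze deviation of the viewing (contralateral) eye during
the epoch; the centre is the circular mean. Screen-gaze sign convention: a
nasal rotation of the left eye points gaze rightward (+), of the right eye
leftward (−). The correction is validated by construction (a +10°
conjugate gaze shift moves the recovered centre by −10°), not against
external data.

## Premotor assemblies

For each convergent saccade the **pre-conv** window is the 3 frames
(3/1.8 ≈ 1.65 s) ending at the frame before the saccade frame, and the
**peri-conv** window the 5 frames (≈2.75 s) centred on it; the saccade
frame is the imaging frame containing the saccade onset (floor division
from the eye clock). Evoked events are compared against the same
epoch-relative frames pooled across non-response trials of the same
stimulus (≥3 required); spontaneous events against the remainder of their
own epoch. The test statistic is a two-sample *pooled-variance* t-test on
frame values. The pooled form matters: with only 3–5 response-window
values, a Welch test loses essentially all power whenever the burst covers
part of the window (the window variance explodes), while the pooled test
borrows the noise variance from the comparison frames and stays calibrated
under the null because both sides share that variance. Frame pooling
versus per-trial summaries was an open choice; frame pooling is the
default and the per-trial route can be built from the exported windows.
Cells pass at p < 0.05 **and** SNR > 3.

Modulated SPV cells are grouped per hemisphere ("unilateral" is enforced
by running detection within each hemisphere separately): a 2-SD covariance
ellipse is fit to the centroids; while area/cell > 533 µm² the farthest
cell in Mahalanobis distance is dropped and the ellipse refit; an assembly
requires ≥ 6 remaining cells, boundary values accepted exactly. Collinear
centroid sets get a 1 µm minimum-axis floor.

**Lead time**: the population trace is the mean of max-normalised member
ΔF/F over the event epoch; the threshold is the pre-stimulus baseline mean
+ 2 SD (frames 1–3; the multiplier was an open choice), crossings are
strict upward crossings, and the lead is the saccade frame minus the onset
of the suprathreshold run active at (or nearest before) the saccade frame —
the run leading into the saccade, not an unrelated earlier transient.
Noiseless planted bursts recover their lead exactly. **Intra-assembly
correlation** is leave-one-out: each member against the mean of the rest,
summarised as median and IQR. **FDR** circularly shifts every ROI's full
trace by one common seeded offset of ≥ 2 epochs (preserving inter-cell
correlations while destroying event alignment; per-ROI shifts are an
option), re-runs the identical detection, and reports mean shuffled count
over original count, averaged over 5 permutations by default.

## The synthetic-data generator

The generator emulates the assay's structure, with defaults fixed at the
experiment's stated conditions: 5–8 pseudo-random repetitions of the 18
stimuli per plane; spots appearing at ±100° and sweeping 200° at 15 or
30 °/s; dark-spot epochs carrying a background-luminance step from 2 s
before spot onset to 2 s after offset; evoked responses Bernoulli per the
logistic model, timed so the spot is near the azimuth drawn from a
truncated normal centred at −5.6° (SD 30°, configurable); vergence changes
N(19.03°, 9.3°) truncated at 0 (a convergent saccade increases vergence by
definition; the SD derives from the reported SEM 0.49 × √361); a fixed +3°
extra rotation of the eye contralateral to the spot (only the direction of
this effect is reported empirically; the magnitude is a choice);
spontaneous convergences Poisson at 1.89/hr outside stimulus windows.
Saccades are 100 ms linear nasal ramps with sub-150 ms binocular
asynchrony, a 2 s hold, and a slow return; fixation noise is low-passed
white noise (SD 0.2°). Waveform shape and noise statistics are not
empirically constrained — they are placeholders exposed in
`behavior_params()`.

Cell populations are placed in a schematic 2-D map (left/right tectal SPV
and neuropil, habenulae, torus longitudinalis, posterior-commissure
landmark): luminance-ON cells enriched 41% in the TL; mixed-selectivity
and NLMS cells in the SPV with hemisphere-appropriate receptive fields;
assembly cells as compact unilateral SPV groups of 8–15 cells within a
30 µm radius. Mixed-selectivity archetypes occupy narrow retinotopic bands
(subtype-specific centre, SD 6°, mirrored across hemispheres) so that an
archetype's members share response timing — the property that makes them a
coherent cluster; NLMS cells keep broad RFs (10–80°) because their
analysis uses timing-free peak vectors. Fluorescence is a sparse train of
latent impulses (spot crossing the cell's RF azimuth, luminance
transitions, or a premotor burst starting `lead_frames` before the
assigned saccade frame) convolved with a difference-of-exponentials
indicator kernel (rise 0.1 s, decay 1.5 s — generic fast-indicator values,
configurable) on the 1.8 Hz frame grid, plus white Gaussian noise (SD 0.1
ΔF/F). Movies render ROIs as disks with brightness F₀(1 + ΔF/F) and
optional per-frame rigid shifts.

What the generator does **not** emulate: tail movements, 3-D screen
optics (spot geometry is collapsed to 1-D azimuth; Weber contrast is
stored as metadata only), photon noise, bleaching, neuropil
contamination, and negative-going luminance responses interact only
crudely with the responsiveness gate. Passing tests therefore demonstrate
correctness of the analysis chain under a faithful but idealised forward
model, not performance on real tissue.

## Problem sizes and numerical choices

The test suite runs entirely on synthetic data at sizes chosen to keep the
full suite under ~3 minutes on one CPU: behavioural recovery at 20,000
trials per stimulus; detector-oracle equivalence on 10⁴-sample traces;
clustering recovery on 600 planted VRVs (3 archetypes × 200 cells, 8
fish); NLMS assignment on ~400-ROI experiments and model comparison on 120
planted cells; assembly recovery on a 260-ROI experiment with 13 planted
assemblies over 144 epochs; spontaneous-rate recovery on 100 h of eye
traces. Fixture noise levels are stated in each test; the planted-VRV
clustering test uses per-point noise at 35% of the template SD, which puts
expected within-archetype correlation near 0.9 — comfortably above the
0.75 threshold yet far from degenerate.

Numerical details worth knowing: every stochastic function takes an
explicit seed and restores the caller's RNG state; correlations of
zero-variance vectors are treated as non-matches rather than NaNs;
truncated normals use inverse-CDF sampling (exact); the discrete calcium
kernel is evaluated at frame centres and normalised to unit peak, so an
impulse registers at its own frame (lead times are exact on noiseless
data); tie-breaks in regressor assignment follow a fixed documented key
order.

## Known limitations

* The segmentation and responsiveness criteria are compact stand-ins, not
  reimplementations of a published pipeline stage.
* Negative-modulation (inhibited) cells fail the peak-based
  responsiveness gate.
* The assembly t-test pools frames within one response trial, so its
  degrees of freedom are few; power therefore depends on burst/window
  overlap (a lead-2 burst covers 2 of 3 pre-conv frames and is genuinely
  harder to detect than a lead-3 burst).
* Eye-position correction of receptive fields assumes purely horizontal,
  conjugate-measurable gaze and a median-rest reference.
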