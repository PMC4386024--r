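# preytect

Analysis of visuomotor transformations during larval zebrafish hunting.

Larval zebrafish initiate hunting with a stereotyped **convergent saccade**
— a rapid nasal rotation of both eyes that increases the vergence angle by
roughly 19°. In a tethered "virtual hunting" assay, a fish views a panel of
18 visual stimuli (16 moving spots spanning a 2×2×2×2 factorial of binary
features — direction, speed, size, contrast polarity — plus two whole-field
flashes, one stimulus per 32 s epoch) while horizontal eye position is
tracked at 60 Hz and tectal calcium activity is imaged at 1.8 Hz. `preytect`
implements the full analysis chain for this experiment:

- **Behaviour** — convergent-saccade detection (binocular nasal rotations
  with onsets within 150 ms), saccade kinematics, evoked/spontaneous
  classification, response-location statistics, and the behavioural
  **feature-compound model**

  `logit(R) = β₀ + β₁·size + β₂·polarity + β₃·speed·size·polarity`

  fit by maximum likelihood with Wald CIs, odds ratios `exp(β)`,
  bidirectional stepwise term selection, and a cross-validated R² on
  per-stimulus response rates.
- **Imaging front end** — rigid frame registration, soma-scale ROI
  segmentation, ΔF/F with per-epoch baselines, and a visual-responsiveness
  gate (per-stimulus t-test at p < 0.05 plus SNR > 3).
- **Tuning** — 684-point visual response vectors (18 stimuli × 38 frames),
  correlation-threshold clustering (members must correlate ≥ 0.75 with the
  cluster centroid and span ≥ 6 fish), feature selectivity indices, and
  anatomical distributions.
- **Non-linear mixed selectivity (NLMS)** — six binary conjunction
  regressors (all selective for large, dark spots), correlation assignment
  at ≥ 0.75, and an equal-complexity comparison of a linear model
  (`y ~ dir + speed + size + pol`) against a non-linear interaction model
  (`y ~ size·pol + speed·size·pol + dir·size·pol + dir·speed·size·pol`),
  scored by cross-validated R² and summarised as
  `SI_nlin = (cvR²_nlin − cvR²_lin) / (|cvR²_nlin| + |cvR²_lin|)`.
- **Premotor assemblies** — convergence-triggered response modulation in a
  3-frame (≈1.65 s) pre-saccadic window and a 5-frame (≈2.75 s)
  saccade-centred window, spatial assembly detection per tectal hemisphere
  (2-SD covariance ellipse, ≥ 6 SPV cells at ≤ 533 µm²/cell), lead times,
  intra-assembly correlations, circular-permutation false-discovery
  estimation, and ipsi/contra oculomotor statistics.
- **Synthetic experiments** — a fully seeded generator (stimulus schedules,
  binocular eye traces with planted saccades, anatomically placed cell
  populations with known tuning, fluorescence forward model, optional TIFF
  movies) that provides ground truth for every stage.

## Worked example

```r
library(preytect)

## a complete synthetic session: 90 epochs, 5 reps of each stimulus
sched  <- generate_schedule(n_planes = 1, reps = 5, seed = 1)
eyes   <- generate_eye_traces(sched, behavior_params(), seed = 2)
events <- classify_evoked(detect_convergent_saccades(eyes), sched)
events[, c("t_onset", "d_left", "d_right", "dvergence", "evoked")]
#>     t_onset    d_left   d_right dvergence evoked
#> 1  268.3333 18.927187 18.955810  37.88300  FALSE
#> 2  318.7167 15.190329 15.203818  30.39415  FALSE
#> 3 1609.1000  8.044489  5.066727  13.11122   TRUE
#> 4 2215.7500 11.283541 14.267880  25.55142   TRUE
#> 5 2635.6167  8.893595 11.861823  20.75542   TRUE
```

Five convergent saccades were detected; two fell outside stimulus
presentation (spontaneous), three were evoked. Per-eye displacements and
the vergence change (`d_left + d_right`, here 13–38°) come from 200 ms
pre/post window means.

```r
## refit the behavioural model to 20,000 simulated trials per stimulus
trials <- simulate_response_trials(20000, seed = 11)
fit <- fit_logistic_model(trials)
fit
#> Hunting-response logistic model
#>   logit(R) ~ size + polarity + speed:size:polarity
#>                       coef    se  ci_lo  ci_hi odds_ratio
#> (Intercept)         -6.490 0.053 -6.594 -6.385      0.002
#> size                 1.305 0.041  1.224  1.386      3.688
#> polarity             1.857 0.048  1.763  1.951      6.404
#> speed:size:polarity  0.902 0.032  0.838  0.965      2.463

predict_response_rate(fit, c(0, 1, 1, 1))   # large, dark, fast spot
#> [1] 0.081
```

The recovered coefficients sit within sampling error of the generating
values (1.33, 1.87, 0.90): large spots raise the odds of a hunting response
~3.7-fold, dark spots ~6.4-fold, and the large∧dark∧fast conjunction a
further ~2.5-fold, giving a ~8% response rate for the best prey-like
stimulus. `run_pipeline(pipeline_config(...))` chains all stages (behaviour,
responsiveness, clustering, NLMS, assemblies) on one synthetic experiment
and returns a report bundle.

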