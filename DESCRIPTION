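Package: preytect
Title: Virtual Hunting Assay and Tectal Population Imaging Analysis for
    Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing visuomotor transformations during larval
    zebrafish hunting. Implements eye-trace analytics for a tethered virtual
    hunting assay (binocular convergent-saccade detection, saccade kinematics,
    logistic feature-compound response models with stepwise selection and
    cross-validation), a two-photon calcium imaging front end (rigid
    registration, ROI segmentation, dF/F, visual-responsiveness gating),
    visual response vectors with correlation-threshold clustering and feature
    selectivity indices, regressor-based identification of non-linear
    mixed-selectivity tectal neurons with equal-complexity linear/non-linear
    model comparison, and convergence-triggered detection of premotor tectal
    assemblies with circular-permutation false-discovery estimation. A fully
    seeded synthetic-experiment generator (stimulus schedules, binocular eye
    traces, planted cell populations, fluorescence, and movies) provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
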