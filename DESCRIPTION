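Package: seedhsi
Title: Single-Seed Near-Infrared Hyperspectral Imaging Chemometrics
Version: 0.1.0
Authors@R:
    person("Seed", "HSI Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Object-wise classification of single seeds from near-infrared
    hyperspectral image cubes. Provides reflectance calibration against
    white/dark reference frames, reverse-mask seed segmentation, per-seed
    mean-spectrum extraction, a composable library of chemometric
    pre-treatments (detrend, asymmetric weighted least-squares baseline,
    Savitzky-Golay derivatives, SNV, EMSC, OSC, mean centring), PLS-DA,
    PLS-compressed RBF C-SVM and single-hidden-layer ANN discriminant
    models with Kennard-Stone splitting and venetian-blinds cross
    validation, genetic-algorithm effective-wavelength selection with an
    RMSECV fitness, and a synthetic seed-image generator so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
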