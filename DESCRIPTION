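Package: cardioslope
Title: Cardiac Contributions to Aperiodic 1/f Spectral Slopes in M/EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolchain for studying how cardiac
    activity contaminates estimates of the aperiodic (1/f) spectral slope in
    electrophysiological recordings. Generates synthetic neural
    (excitation/inhibition convolution model) and cardiac (PQRST-complex plus
    colored noise) time series and multichannel mixtures; estimates power
    spectra (Welch), separates fractal from oscillatory activity (IRASA), and
    fits fixed- and knee-mode aperiodic models with specparam-style peak
    removal across a multiverse of frequency ranges; separates sources with
    FastICA and reconstructs ECG-kept / ECG-rejected / ECG-component
    conditions; quantifies instantaneous cardiac leakage with temporal
    response functions (lagged ridge regression, nested cross-validation);
    and classifies standardized age effects against a region of practical
    equivalence using 94% highest-density intervals. Includes a minimal ECG
    toolchain (cleaning, R-peak detection, time-domain heart-rate
    variability) and an end-to-end synthetic-cohort demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
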