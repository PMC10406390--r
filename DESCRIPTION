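Package: mmoblique
Title: Oblique-Incidence Effects in Backscattering Mueller-Matrix Polarimetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and quantitative analysis of oblique-incidence
    artifacts in backscattering Mueller-matrix (MM) imaging polarimetry.
    Synthesizes MM images of a concentric-fiber anisotropy phantom with
    parameterized incidence-angle distortions (baseline shift, symmetry
    breaking, period degeneracy, phase retardance, element transposition),
    forward-renders and inverts dual-rotating-retarder (DRR) intensity
    acquisitions, extracts azimuthal dependent curves by ring sampling,
    and computes curve statistics (mean, kurtosis, peak/valley metrics,
    frequency distribution histograms) together with FFT harmonic
    amplitudes and the square-wave coefficient Cs used to quantify
    period degeneracy of the central-block MM elements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
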