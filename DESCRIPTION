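Package: nmrkin
Title: Enzyme Kinetics from NMR Progress Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for parameterizing generalized (reversible) Hill rate
    laws from 31P-NMR progress-curve data. Converts free-induction-decay
    (FID) series into calibrated metabolite time courses (exponential
    apodization, Fourier transform, box integration or Lorentzian
    deconvolution, T1 saturation and internal-standard calibration), fits
    smoothing splines to progress curves and differentiates them to obtain
    reaction rates, globally fits rate laws to pooled rate samples with a
    genetic-algorithm search refined by Levenberg-Marquardt least squares
    (with covariance-based standard errors and goodness of fit), scans the
    stability of fits under truncation of near-equilibrium data, and
    validates fitted parameters by simulating a minimal coupled
    phosphoglucose isomerase / phosphofructokinase model with
    Mg-nucleotide rapid equilibria. Includes a synthetic-data module that
    generates noisy progress curves and synthetic FID series from known
    kinetic parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
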