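Package: itckin
Title: Enzyme Kinetics from Isothermal Titration Calorimetry and
    Spectrophotometric Initial Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers Michaelis-Menten kinetic parameters of enzymes acting on
    spectroscopically intractable substrates from isothermal titration
    calorimetry (ITC) thermograms. Implements the single-injection apparent
    enthalpy calibration, conversion of differential thermal power to
    reaction rate and of cumulative heat to residual substrate
    concentration, thermogram conditioning (baseline estimation, Tian
    instrument-response deconvolution, peak integration), nonlinear
    Michaelis-Menten regression with Lineweaver-Burk diagnostics, and the
    companion spectrophotometric initial-rate workflow based on the
    Beer-Lambert law. A seeded calorimeter simulator generates realistic
    thermograms from known ground-truth kinetics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
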