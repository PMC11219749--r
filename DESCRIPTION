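Package: phasemix
Title: Thermodynamic Miscibility Screening for Binary Polymer-Surfactant
    Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs molar Gibbs free energy of mixing profiles from
    composition-resolved chemical potentials of binary polymer-surfactant
    (excipient) systems, locates binodal, spinodal and mechanical/chemical
    mixture critical points by smoothing-spline differentiation, and
    cross-validates detected stability limits against a one-parameter
    Margules activity-coefficient model.  Includes a desk-scale Bennett
    acceptance ratio estimator for free-energy differences between
    alchemical coupling windows, a convergence gate on chemical-potential
    uncertainties, and a synthetic generator of free-energy-perturbation
    style chemical-potential profiles with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
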