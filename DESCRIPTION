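Package: coflow
Title: Blood Viscoelasticity from Coflowing Microchannel Interface Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-compliance coflow viscoelastometry of blood in a
    shallow rectangular microchannel. A lumped fluidic-circuit model of the
    blood/reference coflow (hydraulic resistances, two compliance elements)
    yields a second-order governing equation for the stream interface; the
    package provides the forward model (analytic two-exponential transients
    and stiff nonlinear integration), empirical correction-factor
    calibration, the inverse pipeline that extracts blood viscosity from
    steady interface values and the two compliance coefficients from the
    switch-off decay, Otsu-based interface extraction from microscope image
    stacks, and a synthetic-experiment generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    png
Config/testthat/edition: 3
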