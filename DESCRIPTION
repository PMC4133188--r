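Package: penpress
Title: Subcutaneous Tissue Counter Pressure from Insulin Pen Click Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Non-invasive estimation of the counter pressure that
    subcutaneous tissue exerts against fluid injected from a spring-driven
    insulin pen. The pen emits an audible click for every fixed volume
    increment delivered; the inter-click intervals give the flow rate, and
    the drop in flow between reference injections in air and injections in
    tissue gives the pressure at the needle outlet through a Poiseuille plus
    kinetic-energy pressure balance for the device. A spherically symmetric
    poro-elastic pressure-diffusion model (Darcy flow with a linear
    pressure-porosity law) predicts the tip pressure from the measured flow,
    and bounded least squares in log space recovers the tissue permeability
    and effective bulk modulus. Includes click detection from audio,
    spring-curve and needle-radius calibration, cohort summaries, a coupled
    device-tissue forward simulator for validation, and a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
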