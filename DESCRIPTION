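Package: peripump
Title: Cascade Peristaltic Pumping of Gelling Fluids in Narrow Tubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transient axisymmetric simulator for single and cascade (multi-unit)
    peristaltic pumping of viscous and slowly gelling fluids in narrow flexible
    tubes, in the lubrication (long-wavelength) regime. Provides traveling-occlusion
    waveforms, Newtonian, power-law and time-gelling rheology, a quasi-static
    pressure-flow solver with reservoir boundary conditions, meridional velocity
    field reconstruction with the full nine-component velocity-gradient tensor,
    strain-rate metrics (in-plane shear, extensional strain, total shear-rate
    magnitude) with plane extraction and area-weighted frequency distributions,
    occlusion calibration to matched actuation or shear anchors, and a lumped
    residence-time gelation and clogging model for comparing pumping configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
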