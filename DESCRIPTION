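Package: loinheat
Title: Multistage Heat-Transfer Modelling for Salted-Smoked Pork Loin Processing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Transient axisymmetric heat conduction modelling of cylindrical
    meat products (salted-smoked pork loin, "Hamburgerryg") through a
    multistage industrial process: drying, smoking, steam-cooking,
    water-cooling, air-cooling and the transfer steps between chambers. The
    process is represented as a piecewise-constant schedule of convective
    (Robin) boundary conditions; the conduction equation is solved with a
    conservative finite-volume discretization and implicit time stepping,
    verified against an analytic finite-cylinder eigenfunction series.
    Includes composition-based thermophysical property estimation
    (parallel/perpendicular conductivity mixture rules), least-squares
    calibration of heat-transfer coefficients from centre-probe temperature
    loggers, cold-/hot-spot tracking, validation metrics, and a seeded
    synthetic logger generator emulating pallet- and layer-dependent
    process-temperature variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
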