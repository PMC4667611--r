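Package: swimpressure
Title: Pressure Fields, Surface Forces and Propulsive Efficiency from
    Planar Velocimetry of Swimming Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes gauge-pressure fields from time-resolved planar
    velocimetry (PIV) data by median-of-eight-path integration of the
    Navier-Stokes momentum balance, extracts body-contour kinematics
    (surface velocity, body surface rotation, body surface vorticity),
    decomposes surface pressure forces into forward/rearward pull and
    push components, and evaluates Froude-type hydrodynamic efficiencies
    of the pulling (suction) and pushing mechanisms of undulatory
    swimmers. Includes analytic flow cases with known pressure and a
    synthetic swimmer generator so the whole chain is testable without
    laboratory recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    data.table,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
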