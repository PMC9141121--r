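Package: archforce
Title: Orthodontic Archwire Stiffness Calibration and Force Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the elastic force system delivered by a nitinol
    orthodontic archwire. Provides a virtual load-deflection laboratory
    built on a three-dimensional space-frame beam finite-element solver,
    calibration of the position-dependent elastic constant k(y) along the
    wire, exact degree-6 polynomial interpolation of k(y) through seven
    calibration nodes, per-bracket elastic force evaluation F = k(y) * x^n
    from measured arc-length coordinates and deformations, and a linear
    elastic tetrahedral solver that maps the resulting displacement,
    strain, von Mises stress and strain-energy fields over a synthetic
    tooth-and-bone geometry. Ships the reference calibration tables of a
    clinical straight-wire case as plain-text fixtures and audits its own
    reproduction of them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
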