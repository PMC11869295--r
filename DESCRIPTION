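Package: stringpcet
Title: Finite-Temperature String Method and Charge-Transfer Kinetics for
    Proton-Coupled Electron Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale mechanism analysis of superoxide oxidase style
    charge-transfer chains. Provides analytic surrogate two-dimensional
    proton-transfer energy surfaces with seeded restrained Langevin sampling,
    a finite-temperature string method with polynomial/spline refitting and
    equal-arclength reparameterization, free-energy reconstruction from
    umbrella windows by 2D WHAM, MBAR and a variational maximum-likelihood
    profile with block-bootstrap uncertainties, the Moser-Dutton electron
    tunneling ruler with transition-state-theory conversions and Nernst
    concentration corrections, a chemical master-equation model of the
    superoxide-to-quinol two-electron cycle, and membrane trajectory ensemble
    statistics (axial densities, radial distributions, site occupancies,
    center-of-mass distance series).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
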