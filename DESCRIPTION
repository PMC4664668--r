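Package: minibeamtx
Title: Design Calculations for Charged-Particle Minibeam Radiation Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the physics underlying minibeam radiation therapy with
    protons, light ions and carbon ions: Bethe stopping power and CSDA range in
    water, Fermi-Eyges multiple-Coulomb-scattering transport of sub-millimetre
    minibeams with a Monte Carlo cross-check, lateral dose synthesis of planar
    and pencil minibeam arrays with peak-to-valley dose ratio and merge-depth
    analysis, analytic Bragg curves and spread-out Bragg peak construction, and
    geometry plus dose bookkeeping for interleaved minibeam array treatment
    plans, including collimator yield and incident-dose dilution arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
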