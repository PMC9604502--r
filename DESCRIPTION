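Package: micromkm
Title: Microdosimetric Kinetic Model Predictions of Clonogenic Survival and RBE
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts exposure-specific linear-quadratic survival terms
    (alpha, beta) and the relative biological effectiveness (RBE) of ion
    beams from microdosimetric lineal-energy spectra, using a
    non-Poisson-corrected microdosimetric kinetic model (MCF MKM) in which
    every cell-line parameter is derived a priori from photon dose-response
    data and karyotypic or morphologic information.  Includes lineal-energy
    spectrum containers with synthetic generators (delta, track-segment
    chord-length, log-normal), a priori derivation of nucleus and domain
    radii from mean DNA content, survival-database filtering rules, batch
    RBE tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
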