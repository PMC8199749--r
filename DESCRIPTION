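Package: npdef
Title: Dose Enhancement by High-Z Nanoparticles Under Kilovoltage X-Rays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical evaluation of the absorbed-dose enhancement produced by
    high atomic number nanoparticles (Cu to Bi2O3) suspended in water and
    irradiated with kilovoltage X-rays. Ships per-element photon mass
    attenuation and mass energy-absorption coefficient tables (1-300 keV) with
    log-log interpolation and the elemental mixture rule; computes dose
    enhancement factors for monochromatic and binned polychromatic spectra,
    beam-quality metrics (average energy, aluminium half-value layer,
    effective energy), depth attenuation and beam hardening in water; includes
    a parametric X-ray tube spectrum generator (Kramers continuum,
    characteristic anode lines, Beer-Lambert filtration) for building spectrum
    libraries, survey summaries over material/spectrum/depth grids, and a
    primary-beam model of a nanoparticle-loaded spherical tumour in a water
    phantom.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
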