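Package: phytotherm
Title: Physicochemical Modeling of Phytochrome-Mediated Photothermal Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Black-body spectral analysis of plant environmental temperatures
    and a physicochemical model of phytochrome photothermal sensing. Implements
    Planck spectral energy density and plane irradiance, diluted solar spectral
    irradiance, Wien peak-wavelength and Stefan-Boltzmann integral checks,
    infrared (IR) photon fluxes and the relative R:IR ratio statistic; a Pfr/Pr
    photoconversion kinetics model with IR-driven dark reversion, half-life and
    Pr/Pfr time courses; ordinary least-squares regression stages linking
    temperature to relative Pfr half-life and hypocotyl length to relative R:IR
    ratio; and a seedable synthetic hypocotyl-length generator for genotype
    archetypes so the regression stage is fully testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
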