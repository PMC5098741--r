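Package: knpsim
Title: Kirchhoff-Nernst-Planck Electrodiffusion of Brain Extracellular Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional electrodiffusion simulator for the extracellular
    space (ECS) of neural tissue. Given per-depth time series of transmembrane
    ionic fluxes and capacitive currents, the Kirchhoff-Nernst-Planck (KNP)
    scheme evolves ECS ion concentrations with Nernst-Planck fluxes through a
    porous medium and derives the extracellular potential at every step from
    Kirchhoff's current law under bulk electroneutrality, bypassing explicit
    charge-relaxation dynamics. Ionic diffusion can be switched off to mimic
    classical volume-conductor modelling. Includes a seeded synthetic
    population-source generator, liquid-junction potential calculators
    (Goldman-Hodgkin-Katz and Henderson), log-binned power spectra with
    power-law fitting, and current-source-density estimation with and without
    the diffusion correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
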