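Package: tmeacid
Title: Acid-Base Models of the Tumor Microenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchy of acid-base models for predicting the chemical
    composition of the tumor microenvironment: closed and gas-open compartment
    carbonic-buffer equilibria, a spherically symmetric ten-solute
    diffusion-reaction spheroid model, and a Krogh-cylinder
    convection-diffusion-reaction model of poorly perfused tissue. Predicts
    extracellular and intracellular pH, CO2, bicarbonate, oxygen, lactate and
    glucose fields for fermentative, respiratory and mixed metabolic
    phenotypes, with optional Na+/H+-exchange pH regulation, Davenport-style
    acid-base trajectories, and a classifier of additive, synergistic and
    antagonistic dual-stress (acidosis x hypoxia) omics responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
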