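Package: sprcoat
Title: Quantifying Peptide Coating of Bacterial Particles from Surface
    Plasmon Resonance Responses
Version: 0.1.0
Authors@R:
    person("Aurora", "Lindqvist", email = "aurora.lindqvist@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating how many ligand molecules (for example,
    anchor-modified epitope peptides) are attached per micron-scale particle
    (for example, a BCG bacterium) from multi-parametric surface plasmon
    resonance (SPR) measurements in the Kretschmann configuration.  Includes
    a p-polarized transfer-matrix model of the layered sensor with resonance
    dip localization, an equivalent-sphere and hexagonal-packing geometry
    model that converts rod-shaped cells into an effective homogeneous
    monolayer, the estimation chain from steady-state angular responses to
    surface coverage, immobilized particle counts, adsorbed mass and
    molecules per particle, plus sensorgram I/O, reference-channel
    subtraction, Langmuir 1:1 simulation and fitting, and a command-line
    pipeline driven by JSON run configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
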