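Package: dynimine
Title: Kinetics and Equilibrium Modelling of Dynamic Imine Cross-Linked Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to extract rate and equilibrium constants of dynamic
    imine (oxime, hydrazone, semicarbazone) formation from time-resolved
    UV-Vis absorbance data, and to propagate those constants into
    predictions of hydrogel cross-link density and shear modulus. Fits a
    reversible equimolar bimolecular second-order model to amine
    consumption traces, solves single-ligand and competitive two-ligand
    binding equilibria via the exact cubic solution, maps the regime where
    adding a weakly binding competitor softens the network, and converts
    between storage modulus and elastically active chain concentration
    under affine and phantom network assumptions. Includes a synthetic
    data generator emulating the spectroscopic acquisition so that the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
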