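Package: memgas
Title: Membrane Permeation, Diffusion, and Cavity-Binding Analysis for Gas Permeants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the transport of small apolar gas molecules
    (such as molecular oxygen) in molecular simulations: transfer free
    energies between solvents from mole-fraction solubilities, membrane
    free-energy profiles by Boltzmann inversion of positional histograms
    with block-average errors, counting-method permeability with the
    inhomogeneous solubility-diffusivity integral as an internal
    cross-check, diffusion coefficients from mean-square displacement with
    the hydrodynamic finite-size (periodic-boundary) correction, and
    protein-cavity binding statistics (event detection with gap merging,
    residence times, occupancies, and binding free energies from density
    ratios). Includes Brownian-dynamics surrogate generators (overdamped
    Langevin on a 1D free-energy profile, Metropolis dynamics in a box of
    square-well cavities, and free diffusion) with exact Boltzmann
    stationary laws, so every analysis stage can be validated at desk
    scale without a molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
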