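Package: poreflux
Title: Water Permeation, Free-Energy and Gating Statistics for Channel
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for water transport through membrane channels
    (aquaporin-type pores) from molecular dynamics trajectories. Counts
    end-to-end permeation events through a cylindrical transmembrane section,
    estimates the osmotic permeability coefficient pf by the collective
    diffusion method with a free-energy-barrier (Dk) correction, derives
    occupancy-based Gibbs free-energy profiles along the pore axis, converts
    ligand binding free energies to dissociation constants, and computes
    structural observables (hydrogen bonds, minimum distances, simplified pore
    radius profiles, radial distribution functions, dipole moments, membrane
    potential). A block-based statistical pipeline classifies channels into
    functional states and tests ligand-state association. Includes a
    Brownian-dynamics generator of synthetic pore trajectories with known
    ground truth so every estimator is testable without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
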