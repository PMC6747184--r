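Package: amdtk
Title: Accelerated Molecular Dynamics Boosting, Reweighting and
    Membrane-Pore Analysis on Synthetic Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for the accelerated molecular dynamics
    (aMD) analysis chain: a Langevin engine on analytic toy potentials with
    the dual-boost aMD modification and per-frame boost bookkeeping,
    Maclaurin-series, exponential-average and second-order-cumulant
    reweighting into potentials of mean force, dihedral principal component
    free-energy landscapes with k-means clustering and Kullback-Leibler
    convergence diagnostics, and the standard membrane/pore statistics
    (electron density profiles, acyl order parameters, MSD diffusion, pore
    radius and water occupancy, helicity and bend angles). Every input is
    produced by seeded synthetic generators with known ground truth - a
    two-state bent/linear helical peptide, a pseudo-lipid bilayer slab with
    prescribed acyl order, Brownian waters of known diffusion coefficient,
    and a cylindrical pore - so each estimator can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
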