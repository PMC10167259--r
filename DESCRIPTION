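Package: destraj
Title: Trajectory Analysis for Fatty-Acid Deep Eutectic Solvents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural, hydrogen-bond, energetic and transport analysis of
    molecular-dynamics trajectories of deep eutectic solvents formed by
    choline chloride and fatty acids in water. Provides readers for extended
    XYZ and multi-model PDB trajectories with orthorhombic periodic boxes,
    site-site radial distribution functions with coordination numbers,
    angular and combined (distance/angle, distance/distance) distribution
    functions, spatial distribution functions in a molecule-fixed frame,
    geometric hydrogen-bond detection with Gaussian count statistics and
    per-pair occupancy, pairwise Coulomb and Lennard-Jones group-group
    interaction energies with a relative stability factor, mean-square
    displacement with beta-exponent regime detection and Einstein
    self-diffusion, velocity autocorrelation functions with collision and
    randomization times, bond-vector reorientation dynamics, and Green-Kubo
    shear viscosity from off-diagonal stress autocorrelation. A synthetic
    trajectory generator with known ground truth (ideal gas, planted
    donor-H-acceptor geometries, Brownian and ballistic motion,
    Ornstein-Uhlenbeck velocity and stress processes, rigid rotors, and a
    coarse toy solvent mixture) makes every analysis verifiable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
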