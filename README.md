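# destraj

Trajectory analysis for deep eutectic solvents (DESs) built from choline
chloride and fatty acids, aimed at the question these mixtures pose in
practice: how stable is the hydrogen-bond network between the hydrogen-bond
acceptor (HBA, the [Ch+][Cl-] salt) and the hydrogen-bond donor (HBD, a
fatty acid such as caprylic or lauric acid) once water is around?

The package is for molecular-simulation practitioners who have
configurations or trajectories (extended XYZ or multi-model PDB, plus a
site-parameter table) and want the full structural / hydrogen-bond /
energetic / transport analysis suite as reusable, tested R functions — and
for method developers, who get a synthetic-trajectory generator with known
ground truth so every estimator can be validated without running any MD.

## What it computes

**Structure.** Site–site radial distribution functions g(r) under periodic
minimum-image conventions, with the coordination number

    CN = 4 π ρ ∫₀^r_min1 g(r) r² dr

integrated to the first minimum of g(r); angular distribution functions
ADF(α) with the 1/sin α solid-angle correction; combined distribution
functions (distance/angle and distance/distance 2D histograms, TRAVIS-style
unit-maximum normalization); and spatial distribution functions (3D voxel
densities in a molecule-fixed frame defined by three anchor sites).

**Hydrogen bonds.** Geometric detection of D–H···A bonds (H···A distance
cutoff plus an inclusive D–H···A angle window at the hydrogen), with
presets for the two acceptor chemistries of these mixtures: chloride
(105–120°) and hydroxyl oxygen (150–180°). Per-frame count series are
summarized by a Gaussian fit

    F(X) = a/(σ√2π) · exp(−(X − X̄)² / 2σ²)

whose X̄ is the average number of hydrogen bonds, and per-pair percent
occupancy measures how persistent each individual bond is.

**Energetics.** Group–group nonbonded energies by direct minimum-image
pair sums: Coulomb k_e Σ q_i q_j / r_ij (k_e = 332.0636 kcal·Å/mol·e²) and
12-6 Lennard-Jones Σ D₀ᵢⱼ[(R₀ᵢⱼ/r)¹² − 2(R₀ᵢⱼ/r)⁶] with Lorentz–Berthelot
combination, and the relative stability factor

    S = IE(HBA−HBD) / [ IE(HBA−water) + IE(HBD−water) ]

— the scale-free ratio that quantifies how well the eutectic pair resists
disruption by water.

**Dynamics.** Mean-square displacement by multiple time origins on
unwrapped coordinates, the β exponent β = d log₁₀ MSD / d log₁₀ τ for
regime detection, Einstein self-diffusion D = slope/6 inside the diffusive
window (β ≈ 1); normalized velocity autocorrelation functions with first
and second zero crossings (mean collision and randomization times);
bond-vector reorientation dynamics VRD(τ); and Green–Kubo shear viscosity
η = V/(k_B T) ∫ ⟨P_xy(0) P_xy(t)⟩ dt from off-diagonal stress series.

**Synthetic ground truth.** `gen_ideal_gas()`, `gen_planted_geometry()`,
`gen_brownian()`, `gen_ballistic()`, `gen_ou_velocity()`,
`gen_stress_series()`, `gen_rigid_rotor()` and `gen_toy_des_mixture()`
produce seeded, bit-reproducible inputs whose true parameters (density,
planted geometry, D, γ, A·τ_c, ω, planted hydrogen-bond fraction) are
recorded in metadata.

## Worked example

A toy 50:50 mixture of 100 choline chloride pairs and 100 caprylic-acid
molecules with half of the acids planted in an HA···Cl⁻ contact at 2.0 Å
and 30 waters parked next to free chlorides:

```r
library(destraj)
mix <- gen_toy_des_mixture(n_salt = 100, n_fa = 100, fa_type = "CAP",
                           planted_fraction = 0.5, n_water = 30, seed = 11)

r  <- rdf(mix$trajectory, group_a = list(site = "HA", type = "CAP"),
          group_b = "Cl", dr = 0.07, r_max = 8)
fm <- first_minimum(r)
#> first peak at 1.86 A (g = 50.2), first minimum at 2.21 A, CN = 0.500

hbond_count_series(mix$trajectory, hbond_preset("cl_acceptor"))
#> hbond series: 1 frames, mean count 50.00, 50 unique pairs

er <- interaction_energy_report(mix$trajectory, list(
  salt_water = list(a = list(type = c("CH", "CL")), b = list(type = "WAT")),
  salt_fas   = list(a = list(type = c("CH", "CL")), b = list(type = "CAP")),
  fas_water  = list(a = list(type = "CAP"),         b = list(type = "WAT"))))
er
#>         pair    e_vdw     e_coul   e_total
#> 1 salt_water -7.63996  -497.9346  -505.575
#> 2   salt_fas 67.46952 -1162.2112 -1094.742
#> 3  fas_water -0.51218     1.7242     1.212
stability_factor(er$e_total[2], er$e_total[1], er$e_total[3])
#> [1] 2.171
```

The RDF peak sits in the bin containing the planted 2.0 Å contact, the
hydrogen-bond count equals the planted 50 contacts exactly, the CN to the
first minimum recovers the planted 0.5 contacts per acid, and S falls
monotonically as the planted contacts are diluted (the desk-scale analogue
of water disrupting the eutectic pair).

A config-driven pipeline (`run_pipeline()`, or
`inst/scripts/analyze.R run config.yml`) chains all analyses over one
trajectory and writes CSV/JSON outputs plus a manifest that makes reruns
bit-identical.

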