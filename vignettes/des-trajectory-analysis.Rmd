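---
title: "Structure, hydrogen bonding, energetics and transport in fatty-acid deep eutectic solvents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure, hydrogen bonding, energetics and transport in fatty-acid deep eutectic solvents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Deep eutectic solvents (DESs) are binary mixtures of a hydrogen-bond
acceptor (HBA) and a hydrogen-bond donor (HBD) whose melting point at the
eutectic composition lies far below that of either component. The systems
this package is built around combine choline chloride ([Ch+][Cl-]) as HBA
with a fatty acid — caprylic (CAP) or lauric (LUA) — as HBD. The chloride
anion is the structural hub: the acid's hydroxyl hydrogen (site HA)
donates to Cl- in a short contact near 2.0 Å, while the choline hydroxyl
accepts from the acid in a more linear geometry. Whether that network
survives contact with water decides whether the solvent is useful as a
hydrophobic extraction medium.

`destraj` implements the complete analysis chain used to interrogate such
mixtures — radial/angular/combined/spatial distribution functions,
geometric hydrogen-bond statistics, group–group nonbonded energies with a
relative stability factor, and transport estimators (self-diffusion,
velocity autocorrelation, bond-vector reorientation, Green–Kubo
viscosity) — together with a synthetic-data module that generates inputs
with known ground truth. The package deliberately does **not** run
molecular dynamics: force-field parameterization, barostats, Ewald
summation and trajectory propagation are out of scope. Analyses operate on
trajectories supplied by the user or synthesized in-package.

## Data model

A `md_trajectory` holds an `[n_frames, n_atoms, 3]` coordinate array in
Ångström, optional velocities in Å/ps, frame times in ps (strictly
increasing, uniformly spaced to 1e-9 relative tolerance), and one
orthorhombic `simulation_box`. Only orthorhombic cells are supported: the
bulk-solvent boxes these analyses target are cubic, and supporting
triclinic cells would complicate every minimum-image operation for no
gain here. The `md_topology` table assigns each atom a site label (kept
verbatim — the labelling scheme HA/OA/O1/C1/Cl/O is conventional but the
package treats labels as opaque strings), element, molecule id, molecule
type (`CH`, `CL`, `CAP`, `LUA`, `WAT`, `OTHER`), partial charge (e), and
Lennard-Jones parameters D0 (kcal/mol) and R0 (Å). Charges and LJ
parameters are never read from PDB — the format has no standard field for
them — but from a separate CSV keyed by site label.

Units are Å and ps internally; diffusion coefficients are reported in
Å²/ns, the unit customary for these dense liquids.

The extended-XYZ dialect is: atom count line; comment line carrying
`time=<ps>` and `box=<Lx>,<Ly>,<Lz>`; then `element x y z [vx vy vz]`
records written at 8 decimals, so a write/read round trip is lossless well
below 1e-6 Å.

## Structural estimators

**RDF and coordination number.** For site groups A and B,

$$g(r) = \frac{\langle n_B(r, r+\Delta r)\rangle}{\rho_B\, V_{shell}(r)},
\qquad CN(r) = 4\pi\rho_B \int_0^{r} g(s)\, s^2\, ds .$$

Bins are half-open $[r, r+\Delta r)$ with the value reported at the bin
center and $\Delta r = 0.05$ Å by default. Shell volumes are exact
($\tfrac{4}{3}\pi[(r+\Delta r)^3 - r^3]$), so an uncorrelated homogeneous
system gives $g \equiv 1$ in expectation bin by bin. Intramolecular pairs
are excluded by default: the site–site correlations of interest (HA–Cl,
HA–O) span molecules. Cross-group normalization uses the density of group
B; when A and B are the same group the density uses $N-1$ (ordered-pair
counting). $CN(r)$ is accumulated from the exact per-bin pair counts —
the binned-measure form of the integral above — so it agrees with direct
neighbor counting to machine precision at bin edges and is interpolated
within a bin. Integrating a smoothed $g$ by trapezoid instead would
introduce $O(\Delta r^2)$ discrepancies against the count it is supposed
to represent.

**First minimum.** The first-shell boundary $r_{min1}$ is the first local
minimum of a moving-average-smoothed $g$ (window 5 bins) after the first
peak. A peak must clear both a fixed threshold (1.05) and, when the RDF
carries its own counting statistics, $1 + 3\sigma_{bin}$ with
$\sigma_{bin} = 1/\sqrt{\text{expected count}\times\text{window}}$:
sparse small-$r$ bins of a dilute system fluctuate strongly, and without
the significance guard an ideal gas would occasionally "grow" a shell out
of noise. A monotone or featureless $g$ yields a no-shell result rather
than an error.

**ADF.** Vertex angles of site triples (a, b, c) passing two distance
cutoffs are histogrammed (1° bins by default) and corrected by
$1/\sin\alpha$ to remove the solid-angle measure. The correction is
evaluated at bin centers, not per sample: a collinear triple has
$\alpha = 180°$ exactly, where the per-sample weight diverges, while the
bin-center correction stays finite and books the triple in the last bin.
Angles are computed as `atan2(|u × v|, u·v)`, stable near 0° and 180°.
The density is normalized to unit trapezoid integral over the angle axis.

**CDFs.** The combined distance/angle function matches instances of a
(reference molecule, target atom) pair sharing the anchor atom between
the two observables — e.g. the HA(acid)···Cl distance against the
C1–O1···Cl angle — and accumulates a 2D histogram; distance/distance CDFs
match (reference molecule, target molecule) instances. Following the
display convention of trajectory analyzers in this field, the 2D density
is normalized to unit maximum with the raw counts retained in the result,
so marginals can be compared exactly against 1D histograms.

**SDF.** For every reference molecule, target positions are expressed in
a local frame: origin at anchor 1, x-axis toward anchor 2, anchor 3
fixing the xz half-plane (the frame choice is user-configurable because
no single convention is canonical). Near-collinear anchor triples (< 5°
or > 175°) are skipped and counted. Voxel densities (default 0.5 Å
voxels, ±8 Å extent) are averaged over references and frames; the
construction is invariant under rigid motions of each frame by design.

## Hydrogen bonds

A bond D–H···A is counted when the minimum-image H···A distance is below
the cutoff **and** the D–H···A angle at the hydrogen lies in an inclusive
window. The distance is measured hydrogen-to-acceptor, not
donor-to-acceptor: the first-shell HA–Cl peak at ~2.0 Å is an H···A
separation. Two preset windows encode the acceptor chemistries of these
mixtures, 105–120° for chloride and 150–180° for the hydroxyl oxygen,
both within 2.5 Å. The 2.5 Å preset cutoff is the outer edge of the
high-probability region in the combined distance/angle distribution
(2.0–2.5 Å); since detection is strict (`< dmax`), a cutoff at 2.0 Å
exactly would exclude the very geometry that defines the peak. A `loose`
preset (3.5 Å, 120–180°) mirrors the common distance-first convention.

Count series are summarized by a nonlinear least-squares Gaussian fit to
the unit-bin count histogram,
$F(X) = \frac{a}{\sigma\sqrt{2\pi}} e^{-(X-\bar X)^2/2\sigma^2}$,
initialized at the sample mean and standard deviation
(Levenberg–Marquardt via `minpack.lm`). Both the fitted width σ and the
standard error of the mean are reported, since summaries of the form
"X̄ ± u" are ambiguous between the two. A zero-variance series returns a
degenerate-fit flag instead of a fit. Occupancy tracks unique (donor
molecule, acceptor atom) pairs — a donor that swaps between two
equivalent acceptors counts as two pairs — as the percentage of frames in
which each bond is present.

## Energetics and the stability factor

Group–group energies are direct minimum-image pair sums over
intermolecular pairs with no long-range correction:

$$E_{Coul} = k_e \sum_{i<j} \frac{q_i q_j}{r_{ij}}, \qquad
E_{vdW} = \sum_{i<j} D_{0,ij}\left[\left(\frac{R_{0,ij}}{r_{ij}}\right)^{12}
 - 2\left(\frac{R_{0,ij}}{r_{ij}}\right)^{6}\right]$$

with $k_e = 332.0636$ kcal·Å/(mol·e²) and Lorentz–Berthelot combination
($D_0$ geometric, $R_0$ arithmetic; the combination rule is an explicit
argument because conventions differ between force fields). The direct
sum realizes the defining equations literally — the goal is a
reproducible group-interaction measure, not a replica of any particular
MD engine's Ewald electrostatics. An optional cutoff (e.g. 12 Å) is
available; the default sums all minimum-image pairs, appropriate at desk
scale. Atom pairs closer than 1e-6 Å raise a singularity error naming
the pair.

The relative stability factor

$$S = \frac{IE(\mathrm{HBA{-}HBD})}{IE(\mathrm{HBA{-}water}) + IE(\mathrm{HBD{-}water})}$$

is scale-free; with attractive (negative) energies it is positive, and
larger S means the eutectic pair holds together better relative to its
interactions with water. `table2_check()` evaluates S over a CSV of
interaction-energy triples and also verifies that each printed total
equals the sum of its printed components (tolerance 1e-3 kcal/mol, the
printed precision); transcribed published tables contain rows that fail
this internal-consistency check, and those are flagged rather than used.

## Transport and reorientation

**MSD and self-diffusion.** Coordinates are unwrapped by accumulating
minimum-image frame-to-frame displacements — valid whenever per-step
motion stays below half a box edge, which holds by construction for the
synthetic generators and for any sanely sampled liquid trajectory. The
MSD uses all time origins; the log–log slope
$\beta(\tau) = d\log_{10}\mathrm{MSD}/d\log_{10}\tau$ (centered
differences, 5-point smoothing) classifies regimes: β = 2 ballistic,
β = 1 diffusive. The diffusive window is the longest contiguous run with
$|\beta - 1| \le 0.1$ spanning at least 10 lag points — the published
prescription is just "β = 1", so the tolerance and minimum span are this
package's operational rule — and $D = \text{slope}/6$ over that window,
in Å²/ns. Without such a window a non-diffusive flag is returned instead
of a number.

**VACF.** $C_v(t) = \langle V(t)\!\cdot\!V(0)\rangle / \langle
V(0)\!\cdot\!V(0)\rangle$ over all origins (center-of-mass velocities for
molecular input). The first zero crossing (sign change with linear
interpolation) is reported as the mean collision time, the second as the
randomization time; both may be absent.

**VRD.** Bond unit vectors are dotted across lags, averaged over
molecules and origins, and normalized so VRD(0) = 1 (the prefactor in the
defining expression is left undefined in the literature this follows;
normalizing to 1 at zero lag makes curves comparable across species).
Zero-length vectors are skipped and counted.

**Green–Kubo viscosity.**
$\eta = \frac{V}{k_B T}\int_0^\infty \langle P_{xy}(0)P_{xy}(t)\rangle dt$,
estimated per off-diagonal component (xy, xz, yz) with all time origins,
averaged, and integrated by trapezoid. The plateau is the mean of the
running integral over the window where the averaged ACF has decayed below
2% of its initial value; short-run averaging protocols are simulation
procedure, not estimator definition, so the decay rule is used instead
(independent runs can still be averaged upstream). If the ACF never
decays that far the result carries a no-plateau warning with the running
integral intact. Stress units are declared (`kcal_molA3`, `atm`, `bar`,
`Pa`); the conversion $1\,\mathrm{kcal\,mol^{-1}\,Å^{-3}} =
4184/(N_A \cdot 10^{-30})\ \mathrm{Pa} \approx 6.948\,\mathrm{GPa}$ is
applied squared, with ps → s, to report η in mPa·s.

All correlation estimators use direct multiple-origin sums ($O(N \cdot
\text{lag})$), which are exact and fast at the problem sizes this package
targets; an FFT path would have to reproduce them to 1e-9 to be
admissible and is not currently needed.

## The synthetic-data module

Every generator takes an explicit seed and is bit-reproducible; ground
truth is stored in result metadata so recovery tests are self-describing.
Seeding uses R's Mersenne-Twister through a scoping helper that restores
the caller's RNG state; a counter-based generator would offer the same
reproducibility guarantees but is not available in base R, and the
explicit-seed-per-call API preserves the property that matters
(determinism of every generated object).

- `gen_ideal_gas()` — i.i.d. uniform positions: the exact null model for
  g(r) = 1.
- `gen_planted_geometry()` — D–H···A triples at prescribed distance and
  angle (optional Gaussian distance jitter and far-off decoys), one per
  8 Å grid cell so triples cannot contaminate each other's criteria.
- `gen_brownian()` / `gen_ballistic()` — per-axis Gaussian increments of
  variance 2·D·dt (D in Å²/ns) / constant random velocities; both store
  wrapped coordinates and keep the true unwrapped array in metadata so
  the unwrapping logic itself is testable.
- `gen_ou_velocity()` / `gen_stress_series()` — stationary AR(1)
  discretizations of the Ornstein–Uhlenbeck process with exact marginal
  variance and autocorrelation $e^{-\gamma t}$ / $A e^{-t/\tau_c}$; the
  analytic Green–Kubo integral of the latter is $A\tau_c$.
- `gen_rigid_rotor()` — a unit vector rotating in a plane;
  VRD(τ) = cos(ωτ) exactly, deterministic.
- `gen_toy_des_mixture()` — rigid coarse molecules (choline N/O/HO,
  chloride, fatty acid C1/O1/O2/OA/HA, water OW/HW1/HW2) on a
  non-overlapping 8 Å grid, with a controllable fraction of acids planted
  in the chloride-acceptor contact geometry (2.0 Å, 112.5°) and waters
  parked 3 Å from free chlorides with one O–H aimed at the anion. Charges
  and LJ parameters come from a packaged toy table; the OA charges
  (−0.6269/−0.6136-scale) echo the magnitudes quoted for these acids, the
  acid's remaining charges enforce neutrality, and the LJ radii are small
  enough that planted contacts are net-attractive (Coulomb-dominated), as
  in real hydrogen bonds.

What the toy mixture emulates — labelled sites, planted first-shell
geometry, composition ratios (e.g. 700:300 HBA:HBD), a dilution dial that
stands in for water disruption — is exactly what the analyses consume.
What it does **not** emulate: thermal disorder, force-field-accurate
conformations, liquid-state packing, or dynamics (frames are static
copies). Passing tests therefore certify the estimators, not any physical
prediction about real DESs; published absolute values that depend on
50-ns force-field trajectories (coordination numbers, hydrogen-bond
averages, self-diffusion coefficients, viscosities) are intentionally not
reproduction targets. The published worked examples that *are*
arithmetic — the stability factors implied by printed interaction-energy
triples and the additivity of printed components — are reproduced to
1e-4, absorbing printed rounding.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so each check is
statistically decisive: ideal-gas RDF on 1000 atoms × 50 frames (per-bin
3σ bands from Poisson counts), coordination-number and pair-energy
oracles against brute-force double loops at 1e-9 (relative, for the LJ
sums whose overlap terms reach 1e12), ADF isotropy with 1e5 spherical
samples (χ² against the sin α measure, p > 0.01), hydrogen-bond detection
against triple enumeration on 1000 random frames, Gaussian count-fit
recovery of planted means 234 and 427 within 3 standard errors over 5
seeds, Brownian D = 1 Å²/ns recovered within 10% from 200 particles ×
1000 frames, OU VACF at t = 1/γ within 0.05 of e⁻¹ at 1e5 steps,
Green–Kubo η within 10% of V·A·τ_c/(k_BT) at 5e5 steps, rotor VRD to
1e-10, and SDF rigid-motion invariance to 1e-9.

Degenerate inputs are signalled, not silently computed: empty selections,
r_max beyond the half-box, missing boxes, atom-count mismatches (with the
offending frame index), overlapping atoms in energy sums, zero-variance
count series, non-decaying stress ACFs, and monotone RDFs all have
defined behaviors described above.

## Known limitations

- Orthorhombic, constant boxes only; NPT trajectories with fluctuating
  cells must be resampled upstream.
- Direct Coulomb sums are not Ewald electrostatics; group energies are
  comparative measures, not absolute solvation energies.
- Hydrogen-bond donors are paired with hydrogens by shared molecule id
  and site label, not by bond perception; exotic topologies with several
  equivalent hydroxyls per molecule need distinct site labels.
- The pipeline's synthetic input supports the toy mixture only; other
  generators are library functions and a thin `synth` command-line
  wrapper.
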