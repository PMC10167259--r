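# Physical constants used across the package (MD conventions).

# Coulomb prefactor e^2/(4 pi eps0) in kcal * Angstrom / (mol * e^2)
.COULOMB_K <- 332.0636

# Boltzmann constant in kcal/(mol K)
.KB_KCAL_MOL <- 0.0019872041

# Pressure unit conversions to Pascal.
# kcal mol^-1 A^-3 -> Pa: 4184 J/kcal / (N_A * 1e-30 m^3)
.PRESS_TO_PA <- c(
  kcal_molA3 = 4184 / (6.02214076e23 * 1e-30),
  atm = 101325,
  bar = 1e5,
  Pa = 1
)

# Atomic masses (amu) for common elements; coarse sites fall back to 12.
.ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, Cl = 35.45, Na = 22.990, K = 39.098, X = 12.0
)

.element_mass <- function(element) {
  m <- .ELEMENT_MASSES[element]
  m[is.na(m)] <- 12.0
  unname(m)
}
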