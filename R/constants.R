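# Physical constants and unit conversions used throughout.
# Units policy: lengths in Angstrom, times in ns, energies in kcal/mol,
# charges in elementary charges, dipoles in Debye, potentials in mV,
# permeabilities in cm^3 s^-1.

# Gas constant in kcal mol^-1 K^-1 (equals the Boltzmann constant on the
# per-mole energy scale used for kcal/mol free energies).
.R_KCAL <- 1.9872e-3

# kT in kcal/mol at temperature T (Kelvin)
kT_kcal <- function(T) .R_KCAL * T

# One elementary charge times one Angstrom, in Debye.
.EA_TO_DEBYE <- 4.80320425

# e / (eps0 * Angstrom) in volts: the scale factor of the one-dimensional
# Poisson integration when charge density is in e/A^3 and lengths in A.
.E_OVER_EPS0_A <- 1.602176634e-19 / (8.8541878128e-12 * 1e-10)

# Default single-water volume: 18.07 cm^3/mol / Avogadro.
.V_WATER_CM3 <- 2.989e-23

#' Gas constant used for free energy conversions
#'
#' Returns the molar gas constant in kcal mol^-1 K^-1 as used by
#' [kd_from_dg()] and the Gibbs profile machinery.
#' @return Numeric scalar, 1.9872e-3 kcal mol^-1 K^-1.
#' @export
gas_constant_kcal <- function() .R_KCAL
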