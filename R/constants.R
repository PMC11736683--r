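#' Physical constants and unit conventions
#'
#' All internal computations use a single unit system: lengths in angstrom
#' (\enc{Å}{A}), times in picoseconds (ps), energies in kJ/mol, temperatures
#' in kelvin. Conversions to reporting units (cm/s for permeabilities,
#' kg/m^3 for mass densities) happen only at the reporting boundary.
#'
#' `phys_constants()` returns the constants used throughout, optionally
#' overriding the temperature and the permeant molar mass. The default molar
#' mass is 32 g/mol (molecular oxygen); note that coarse-grained bead masses
#' may differ (e.g. 36 g/mol for a Martini tiny bead) — density bookkeeping
#' here deliberately uses the molecular mass.
#'
#' @param temperature simulation temperature in K (default 310)
#' @param molar_mass permeant molar mass in g/mol (default 32, molecular O2)
#' @return a list with components `kB` (kJ/mol/K), `NA_avogadro` (1/mol),
#'   `temperature` (K), `molar_mass` (g/mol) and `kBT` (kJ/mol).
#' @examples
#' phys_constants()$kBT  # ~2.577 kJ/mol at 310 K
#' @export
phys_constants <- function(temperature = 310, molar_mass = 32) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  stopifnot(is.numeric(molar_mass), length(molar_mass) == 1L, molar_mass > 0)
  list(
    kB = .memgas$kB,
    NA_avogadro = .memgas$NA_avogadro,
    temperature = temperature,
    molar_mass = molar_mass,
    kBT = .memgas$kB * temperature
  )
}

# internal constant store (CODATA values)
.memgas <- list(
  kB = 0.008314462618,        # Boltzmann constant, kJ/mol/K (molar gas constant)
  kB_J = 1.380649e-23,        # Boltzmann constant, J/K (per molecule)
  NA_avogadro = 6.02214076e23,# 1/mol
  xi_cubic = 2.837297,        # self-term of the cubic-lattice Ewald sum
  A_per_ps_to_cm_per_s = 1e4, # 1 A/ps = 10^4 cm/s
  m2_per_s_to_A2_per_ps = 1e8 # 1 m^2/s = 10^8 A^2/ps
)

#' Thermal energy in kJ/mol
#'
#' @param temperature temperature in K
#' @return kB * T in kJ/mol
#' @keywords internal
kBT <- function(temperature) .memgas$kB * temperature
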