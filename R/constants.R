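# Physical constants (CODATA 2018) and unit conversions.
# Unit conventions used throughout:
#   lengths/diameters  Angstrom (A)
#   molecular volumes  A^3 per molecule
#   molar volumes      cm^3 mol^-1
#   energies           kJ mol^-1 (outputs), J mol^-1 internally
#   entropies          J K^-1 mol^-1
#   attraction a       kJ cm^3 mol^-2 (molar) or J A^3 (per molecule pair)
# All conversions live in this file.

.const <- list(
  R        = 8.314462618,    # gas constant, J mol^-1 K^-1
  N_Av     = 6.02214076e23,  # Avogadro constant, mol^-1
  kB       = 8.314462618 / 6.02214076e23,  # Boltzmann constant, J K^-1
  h        = 6.62607015e-34, # Planck constant, J s
  atm_Pa   = 101325,         # 1 atm in Pa
  T_ref    = 298.15,         # default reference temperature, K
  rcp      = 0.64            # random close packing volume fraction of spheres
)

#' Physical constants used by the package
#'
#' Returns the constants (CODATA 2018 values) behind every computation:
#' the gas constant `R` (J mol^-1 K^-1), Avogadro's number `N_Av` (mol^-1),
#' the Boltzmann constant `kB` (J K^-1), Planck's constant `h` (J s), one
#' atmosphere in pascal (`atm_Pa`), the default reference temperature
#' `T_ref` = 298.15 K, and the random-close-packing fraction `rcp` = 0.64.
#'
#' @return A named list of numeric constants.
#' @export
#' @examples
#' vdw_constants()$R
vdw_constants <- function() .const

# number density (A^-3) of a liquid with molar volume v1 (cm^3 mol^-1);
# 1 cm^3 = 1e24 A^3
number_density <- function(v1) .const$N_Av / (v1 * 1e24)

# molar volume (cm^3 mol^-1) from a per-molecule volume in A^3
molar_from_molecular_volume <- function(v_A3) v_A3 * .const$N_Av / 1e24

#' Convert an attraction parameter between molar and per-molecule units
#'
#' The van der Waals attraction parameter appears in molar form
#' (kJ cm^3 mol^-2, the unit used by the solvation calculators) or in
#' per-molecule form (J A^3, the unit used by the binary-mixture model).
#' The two are related by `a_molar = N_Av^2 * a_molecular` after converting
#' kJ to J and cm^3 to A^3.
#'
#' @param a_molar Attraction parameter in kJ cm^3 mol^-2.
#' @param a_molecular Attraction parameter in J A^3 (per molecule pair).
#' @return The parameter in the other unit system.
#' @export
#' @examples
#' a_molar_to_molecular(1000)
#' a_molecular_to_molar(a_molar_to_molecular(1000))
a_molar_to_molecular <- function(a_molar) {
  a_molar * 1e3 * 1e24 / .const$N_Av^2
}

#' @rdname a_molar_to_molecular
#' @export
a_molecular_to_molar <- function(a_molecular) {
  a_molecular * .const$N_Av^2 / (1e3 * 1e24)
}

#' Ideal-gas molar volume
#'
#' `RT/P` for an ideal gas, used as the gas-phase endpoint of liberation
#' (molar-volume transfer) free energies.
#'
#' @param T Temperature in kelvin.
#' @param P Pressure in atmospheres.
#' @return Molar volume in cm^3 mol^-1.
#' @export
#' @examples
#' ideal_gas_molar_volume(298.15, 1) # ~24465 cm^3/mol
ideal_gas_molar_volume <- function(T = 298.15, P = 1) {
  stopifnot(T > 0, P > 0)
  .const$R * T / (P * .const$atm_Pa) * 1e6
}
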