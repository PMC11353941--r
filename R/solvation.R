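#' Ben-Naim solvation thermodynamics of a solute in van der Waals liquids
#'
#' Assembles the full solvation result for a solute transferred from a
#' fixed position in the ideal gas to a fixed position in each liquid:
#' the cavity-creation part ([cavity_thermo()]) plus the
#' attraction-switching part ([attraction_thermo()]), with
#' `dG_star = dG_c + dG_a` the Ben-Naim solvation Gibbs free energy.
#' Attraction parameters are rarely tabulated; when either side's
#' `a_attr` is missing the attraction columns are zero-filled and the row
#' flagged (`attraction = FALSE`), with a warning.
#'
#' @inheritParams cavity_thermo
#' @param a_solute Solute attraction parameter, kJ cm^3 mol^-2, or `NULL`.
#'   The solvent parameter is taken from an `a_attr` column of `solvents`
#'   when present.
#' @return A tibble of class `vdw_solvation`, one row per solvent, with
#'   `dG_star` and all cavity/attraction components; energies kJ mol^-1,
#'   entropies J K^-1 mol^-1.
#' @export
#' @examples
#' solvate(builtin_solvents(), sigma_solute = 4)
solvate <- function(solvents, sigma_solute = 4, b_solute = NULL,
                    a_solute = NULL, T = 298.15, T_ref = 298.15) {
  d <- validate_solvents(solvents)
  b2 <- b_solute %||% hard_sphere_b(sigma_solute)
  cav <- cavity_thermo(d, b_solute = b2, T = T, T_ref = T_ref)

  a1 <- if ("a_attr" %in% names(d)) d$a_attr else rep(NA_real_, nrow(d))
  a2 <- a_solute %||% NA_real_
  have_attr <- !is.na(a1) & !is.na(a2)
  if (any(!have_attr)) {
    warn(sprintf(
      "Attraction parameters missing for %d of %d solvent(s); attraction terms zero-filled.",
      sum(!have_attr), nrow(d)))
  }
  v1_T <- molar_volume_at_T(d$v1, d$alpha_P, T_ref, T)
  att <- attraction_thermo(ifelse(have_attr, a1, 0),
                           ifelse(have_attr, a2, 0),
                           v1_T, d$alpha_P, T)

  out <- tibble(
    name = cav$name, T = T, xi1 = cav$xi1,
    dG_star = cav$dG_c + att$dG_a,
    dG_c = cav$dG_c, dH_c = cav$dH_c, dS_c = cav$dS_c,
    dS_x = cav$dS_x, dS_nx = cav$dS_nx,
    dG_a = att$dG_a, dH_a = att$dH_a, dS_a = att$dS_a,
    attraction = have_attr
  )
  structure(out, class = c("vdw_solvation", class(out)),
            b_solute = b2, T_ref = T_ref)
}

#' Solvation free energy from equilibrium number densities
#'
#' At phase equilibrium the Ben-Naim solvation Gibbs free energy follows
#' directly from the ratio of the solute's number densities in the two
#' phases: `dG_star = RT ln(rho_gas / rho_liquid)`. The inverse recovers
#' the density ratio (an Ostwald-type partition coefficient) from a free
#' energy.
#'
#' @param rho_gas,rho_liq Solute number densities in the gas and liquid
#'   phase (any common unit; only the ratio matters). Must be positive.
#' @param dG Solvation free energy, kJ mol^-1.
#' @param T Temperature, K.
#' @return `solvation_dG_from_densities()`: kJ mol^-1.
#'   `density_ratio_from_dG()`: the ratio `rho_gas / rho_liq`.
#' @export
#' @examples
#' solvation_dG_from_densities(exp(1), 1, 298.15) # RT = 2.479 kJ/mol
solvation_dG_from_densities <- function(rho_gas, rho_liq, T = 298.15) {
  if (any(rho_gas <= 0) || any(rho_liq <= 0)) {
    abort("Number densities must be positive.", class = "vdwsolv_domain_error")
  }
  .const$R * T * log(rho_gas / rho_liq) / 1e3
}

#' @rdname solvation_dG_from_densities
#' @export
density_ratio_from_dG <- function(dG, T = 298.15) {
  exp(dG * 1e3 / (.const$R * T))
}

#' Liberation (molar-volume transfer) free energy
#'
#' `RT ln(Vm_from / Vm_to)`: the Gibbs free energy contribution that
#' arises purely from the difference in molar volume between two phases.
#' The Ben-Naim solvation convention (fixed solute positions, molar
#' concentration scale) removes exactly this term; the function makes it
#' explicit. For a gas-phase endpoint use [ideal_gas_molar_volume()].
#'
#' @param Vm_from,Vm_to Molar volumes of the source and destination
#'   phases, cm^3 mol^-1 (positive).
#' @param T Temperature, K.
#' @return Free energy in kJ mol^-1.
#' @export
#' @examples
#' # ideal gas at 1 atm -> water, 25 degC: 17.87 kJ/mol
#' liberation_free_energy(ideal_gas_molar_volume(298.15, 1), 18.07)
#' # n-hexane -> water: 4.92 kJ/mol
#' liberation_free_energy(131.62, 18.07)
liberation_free_energy <- function(Vm_from, Vm_to, T = 298.15) {
  if (any(Vm_from <= 0) || any(Vm_to <= 0)) {
    abort("Molar volumes must be positive.", class = "vdwsolv_domain_error")
  }
  .const$R * T * log(Vm_from / Vm_to) / 1e3
}
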