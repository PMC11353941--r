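#' Cavity-creation thermodynamics in a van der Waals liquid
#'
#' Reversible work to open a solute-sized cavity in each solvent, with its
#' enthalpy/entropy decomposition. In molar form, with liquid number
#' density `rho1 = N_Av / v1` and packing fraction `xi1 = rho1 * b1`:
#'
#' \deqn{\Delta G_c = -RT \ln(1 - \rho_1 b_1) + RT\,\rho_1 b_2 / (1 - \rho_1 b_1)}
#' \deqn{\Delta H_c = RT^2 \alpha_P\,\rho_1/(1-\rho_1 b_1)\,[b_1 + b_2/(1-\rho_1 b_1)]}
#' \deqn{\Delta S_c = R\ln(1-\rho_1 b_1) - R\,\rho_1 b_2/(1-\rho_1 b_1) + \Delta H_c/T}
#'
#' The entropy splits exactly into an excluded-volume part
#' `dS_x = -dG_c/T` (always negative: the cavity restricts solvent
#' translation) and a structural-reorganization part `dS_nx = dH_c/T`,
#' which carries the sign of `alpha_P` and cancels `dH_c` in the free
#' energy — the enthalpy–entropy compensation of the liquid's response.
#' Away from the reference temperature the density is propagated with
#' [molar_volume_at_T()].
#'
#' @param solvents Data frame with columns `v1` (cm^3 mol^-1), `alpha_P`
#'   (K^-1) and `sigma` (A) or `b1` (A^3); optionally `name`. See
#'   [builtin_solvents()].
#' @param sigma_solute Solute hard-sphere diameter in A (default 4, a
#'   xenon-sized cavity). Ignored when `b_solute` is given.
#' @param b_solute Solute repulsive volume parameter in A^3; default
#'   derived from `sigma_solute` via [hard_sphere_b()].
#' @param T Temperature in K.
#' @param T_ref Temperature (K) at which `v1` was measured.
#' @return A tibble with one row per solvent: `name`, `T`, `xi1`, and the
#'   energies `dG_c`, `dH_c` (kJ mol^-1) and entropies `dS_c`, `dS_x`,
#'   `dS_nx` (J K^-1 mol^-1).
#' @export
#' @examples
#' cavity_thermo(builtin_solvents())
cavity_thermo <- function(solvents, sigma_solute = 4, b_solute = NULL,
                          T = 298.15, T_ref = 298.15) {
  d <- validate_solvents(solvents)
  b2 <- b_solute %||% hard_sphere_b(sigma_solute)
  if (b2 < 0) abort("Solute `b` must be non-negative.",
                    class = "vdwsolv_domain_error")
  v1_T <- molar_volume_at_T(d$v1, d$alpha_P, T_ref, T)
  core <- cavity_core(d$b1, b2, v1_T, d$alpha_P, T, name = d$name)
  tibble(name = d$name, T = T, xi1 = core$xi1,
         dG_c = core$dG_c, dH_c = core$dH_c,
         dS_c = core$dS_c, dS_x = core$dS_x, dS_nx = core$dS_nx)
}

# Vectorised cavity formulas in molar units; v1 already at temperature T.
# Energies returned in kJ/mol, entropies in J/K/mol.
cavity_core <- function(b1, b2, v1, alpha_P, T, name = NULL) {
  rho1 <- number_density(v1)
  xi1 <- rho1 * b1
  if (any(xi1 >= 1)) {
    i <- which(xi1 >= 1)[1]
    lab <- if (!is.null(name)) paste0(" (", name[i], ")") else ""
    abort(sprintf(
      "Overpacked liquid%s at T = %.6g K: rho1*b1 = %.4f >= 1 leaves no free volume.",
      lab, T, xi1[i]),
      class = "vdwsolv_overpacked_error")
  }
  R <- .const$R
  free <- 1 - xi1
  ratio <- rho1 * b2 / free
  dG_c <- (-R * T * log(free) + R * T * ratio) / 1e3
  dH_c <- (R * T^2 * alpha_P * rho1 / free * (b1 + b2 / free)) / 1e3
  dS_c <- R * log(free) - R * ratio + dH_c * 1e3 / T
  list(xi1 = xi1, dG_c = dG_c, dH_c = dH_c, dS_c = dS_c,
       dS_x = -dG_c * 1e3 / T, dS_nx = dH_c * 1e3 / T)
}

#' Kinetic part of the van der Waals pressure
#'
#' `RT / (v1 - b1)`, the thermal-motion part of the van der Waals
#' equation of state at liquid density. Multiplying it by the solute
#' volume parameter reproduces exactly the pressure–volume term of the
#' cavity work, which is why the second cavity term can be read as the
#' work of insertion against this internal kinetic pressure. In a dense
#' liquid the free volume `v1 - b1` is small, so the value is thousands
#' of atmospheres.
#'
#' @param v1 Molar volume, cm^3 mol^-1.
#' @param b1_molar Molar repulsive volume, cm^3 mol^-1 (`b1` in A^3 times
#'   `N_Av / 1e24`).
#' @param T Temperature, K.
#' @return Pressure in atm.
#' @export
#' @examples
#' b1m <- hard_sphere_b(2.80) * vdw_constants()$N_Av / 1e24
#' kinetic_pressure(18.07, b1m, 298.15) # several thousand atm
kinetic_pressure <- function(v1, b1_molar, T = 298.15) {
  if (any(v1 <= b1_molar)) {
    abort(sprintf(
      "Overpacked liquid: v1 = %.4g <= b1_molar = %.4g cm^3/mol.",
      v1[v1 <= b1_molar][1], b1_molar[v1 <= b1_molar][1]),
      class = "vdwsolv_overpacked_error")
  }
  # R*T [J/mol] / (cm^3/mol) = 1e6 Pa = J/cm^3
  .const$R * T / (v1 - b1_molar) * 1e6 / .const$atm_Pa
}
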