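#' Attraction-switching thermodynamics
#'
#' Free energy, enthalpy and entropy of switching on the attractive
#' potential between a solute fixed in the liquid and the surrounding
#' solvent molecules, at infinite dilution. With the geometric-mean cross
#' term between the solvent and solute attraction parameters:
#'
#' \deqn{\Delta G_a = -2\sqrt{a_1 a_2}/v_1}
#' \deqn{\Delta S_a = -2\sqrt{a_1 a_2}\,\alpha_P/v_1}
#' \deqn{\Delta H_a = -(2\sqrt{a_1 a_2}/v_1)(1 + \alpha_P T) = \Delta G_a + T\Delta S_a}
#'
#' The `alpha_P`-proportional parts of `dH_a` and `T*dS_a` cancel in
#' `dG_a`: the liquid's structural reorganization in response to the new
#' attractions is enthalpy–entropy compensating, exactly as for cavity
#' creation.
#'
#' @param a1,a2 Solvent and solute attraction parameters in molar units,
#'   kJ cm^3 mol^-2 (non-negative). See [a_molar_to_molecular()] for the
#'   per-molecule conversion.
#' @param v1 Solvent molar volume at `T`, cm^3 mol^-1.
#' @param alpha_P Solvent isobaric expansion coefficient, K^-1.
#' @param T Temperature, K.
#' @return A tibble with columns `dG_a`, `dH_a` (kJ mol^-1) and `dS_a`
#'   (J K^-1 mol^-1).
#' @export
#' @examples
#' attraction_thermo(a1 = 1000, a2 = 1000, v1 = 100, alpha_P = 1e-3)
attraction_thermo <- function(a1, a2, v1, alpha_P, T = 298.15) {
  if (any(a1 < 0) || any(a2 < 0)) {
    abort("Attraction parameters must be non-negative.",
          class = "vdwsolv_domain_error")
  }
  if (any(v1 <= 0)) abort("`v1` must be positive.",
                          class = "vdwsolv_domain_error")
  g <- -2 * sqrt(a1 * a2) / v1              # kJ/mol
  dS <- g * alpha_P * 1e3                   # J/K/mol
  tibble(dG_a = g, dH_a = g * (1 + alpha_P * T), dS_a = dS)
}
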