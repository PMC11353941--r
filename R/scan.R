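#' Solvation thermodynamics across a temperature grid
#'
#' Evaluates [solvate()] at each temperature, propagating the solvent
#' density with the constant-`alpha_P` exponential volume model. With
#' this model the tabulated entropies are the exact temperature
#' derivatives of the free energies, so central finite differences of
#' `dG` columns across a fine grid reproduce the `dS` columns.
#' An overpacked grid point (packing fraction reaching 1 as the liquid is
#' cooled and densified) raises an error naming the temperature.
#'
#' @inheritParams solvate
#' @param T_grid Numeric vector of temperatures in K (all positive).
#' @return A tibble of class `vdw_scan`: one row per solvent per
#'   temperature, with the columns of [solvate()].
#' @export
#' @examples
#' suppressWarnings(
#'   temperature_scan(builtin_solvents()[1, ], T_grid = seq(278, 368, 10))
#' )
temperature_scan <- function(solvents, sigma_solute = 4, b_solute = NULL,
                             a_solute = NULL, T_grid = seq(273.15, 373.15, 5),
                             T_ref = 298.15) {
  if (any(T_grid <= 0)) {
    abort("All grid temperatures must be positive.",
          class = "vdwsolv_domain_error")
  }
  b2 <- b_solute %||% hard_sphere_b(sigma_solute)
  rows <- map_dfr(T_grid, function(Ti) {
    suppressWarnings(
      solvate(solvents, b_solute = b2, a_solute = a_solute,
              T = Ti, T_ref = T_ref)
    )
  })
  structure(arrange(rows, .data$name, .data$T),
            class = c("vdw_scan", class(rows)),
            b_solute = b2, T_ref = T_ref)
}
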