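#' Tidy a solvation result into long form
#'
#' @param x A `vdw_solvation` tibble from [solvate()].
#' @param ... Unused.
#' @return A tibble with one row per solvent per thermodynamic term:
#'   columns `name`, `process` (cavity / attraction / total), `term`,
#'   `estimate`, `unit`.
#' @export
#' @examples
#' fit <- suppressWarnings(solvate(builtin_solvents()))
#' tidy(fit)
tidy.vdw_solvation <- function(x, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(x)[c("name", "dG_star", "dG_c", "dH_c", "dS_c", "dS_x",
                   "dS_nx", "dG_a", "dH_a", "dS_a")],
    -"name", names_to = "term", values_to = "estimate"
  )
  long$process <- dplyr::case_when(
    long$term == "dG_star" ~ "total",
    grepl("_a$", long$term) ~ "attraction",
    .default = "cavity"
  )
  long$unit <- ifelse(grepl("^dS", long$term), "J/K/mol", "kJ/mol")
  long[c("name", "process", "term", "estimate", "unit")]
}

#' One-row summary of a solvation result
#'
#' @param x A `vdw_solvation` tibble from [solvate()].
#' @param ... Unused.
#' @return A one-row tibble: number of solvents, temperature, solute `b`,
#'   number of rows with attraction parameters, and the range of
#'   `dG_star`.
#' @export
glance.vdw_solvation <- function(x, ...) {
  tibble(
    n_solvents = nrow(x), T = x$T[1],
    b_solute = attr(x, "b_solute"),
    n_with_attraction = sum(x$attraction),
    dG_star_min = min(x$dG_star), dG_star_max = max(x$dG_star)
  )
}

#' Tidy a van der Waals mixture state
#'
#' @param x A [mixture_state()].
#' @param ... Unused.
#' @return A tibble of the state's parameters (per-molecule units).
#' @export
tidy.vdw_mixture <- function(x, ...) {
  tibble(
    term = c("b1", "b2", "a1", "a2", "N1", "N2", "V", "T"),
    estimate = c(x$b1, x$b2, x$a1, x$a2, x$N1, x$N2, x$V, x$T),
    unit = c("A^3", "A^3", "J A^3", "J A^3", "", "", "A^3", "K")
  )
}

#' One-row summary of a van der Waals mixture
#'
#' @param x A [mixture_state()].
#' @param ... Unused.
#' @return A one-row tibble with the mole fraction `x2`, free-volume
#'   fraction, excess Helmholtz energy (J), EOS pressure (J/A^3) and the
#'   Ben-Naim standard chemical potential of component 2 (kJ/mol).
#' @export
glance.vdw_mixture <- function(x, ...) {
  A <- helmholtz_energy(x)
  tibble(
    x2 = x$N2 / (x$N1 + x$N2),
    free_volume_fraction = (x$V - x$b1 * x$N1 - x$b2 * x$N2) / x$V,
    A_excess = A$excess,
    pressure = vdw_pressure(x),
    mu2_star_kJmol = chemical_potential(x, 2)$mu_star_kJmol
  )
}
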