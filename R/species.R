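#' Repulsive volume parameter from a hard-sphere diameter
#'
#' Converts an effective hard-sphere diameter into the van der Waals
#' repulsive volume parameter `b` using the random-close-packing
#' convention: the sphere volume `pi * sigma^3 / 6` divided by 0.64, the
#' maximum volume occupancy of randomly packed spheres. For xenon
#' (`sigma = 4` A) this gives 52.4 A^3.
#'
#' @param sigma Effective hard-sphere diameter(s) in Angstrom; must be
#'   non-negative.
#' @return Volume parameter(s) in A^3 per molecule.
#' @export
#' @examples
#' hard_sphere_b(4.0)  # 52.36, prints as 52.4
#' hard_sphere_b(2.80) # water, 17.96
hard_sphere_b <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma))) {
    abort("`sigma` must be finite numeric.", class = "vdwsolv_domain_error")
  }
  if (any(sigma < 0)) {
    abort("`sigma` must be non-negative (hard-sphere diameter).",
          class = "vdwsolv_domain_error")
  }
  (pi * sigma^3 / 6) / .const$rcp
}

#' Describe a chemical species by its van der Waals parameters
#'
#' A species is defined by its effective hard-sphere diameter `sigma` (A)
#' and/or repulsive volume parameter `b` (A^3), an optional attraction
#' parameter `a_attr` (molar units, kJ cm^3 mol^-2), and an optional
#' molecular mass (kg), needed only when absolute (translational)
#' free energies are requested. When both `sigma` and `b` are supplied
#' they must agree with the random-close-packing convention to within
#' 0.1 A^3; when only `sigma` is given, `b` is derived via
#' [hard_sphere_b()].
#'
#' @param name Species label.
#' @param sigma Effective hard-sphere diameter in A (optional if `b` given).
#' @param b Repulsive volume parameter in A^3 (optional if `sigma` given).
#' @param a_attr Attraction parameter in kJ cm^3 mol^-2, or `NULL` if
#'   unknown.
#' @param mass Molecular mass in kg, or `NULL`.
#' @return A one-row tibble of class `vdw_species` with columns `name`,
#'   `sigma`, `b`, `a_attr`, `mass`.
#' @export
#' @examples
#' species_spec("xenon", sigma = 4)
species_spec <- function(name, sigma = NULL, b = NULL, a_attr = NULL,
                         mass = NULL) {
  if (is.null(sigma) && is.null(b)) {
    abort("Supply at least one of `sigma` or `b`.",
          class = "vdwsolv_domain_error")
  }
  if (!is.null(sigma)) {
    b_conv <- hard_sphere_b(sigma)
    if (is.null(b)) b <- b_conv
    else if (abs(b - b_conv) > 0.1) {
      abort(sprintf(
        "`b` = %.3f A^3 is inconsistent with sigma = %.3f A (convention gives %.3f A^3; tolerance 0.1).",
        b, sigma, b_conv), class = "vdwsolv_domain_error")
    }
  }
  if (b < 0) abort("`b` must be non-negative.", class = "vdwsolv_domain_error")
  if (!is.null(a_attr) && a_attr < 0) {
    abort("`a_attr` must be non-negative.", class = "vdwsolv_domain_error")
  }
  out <- tibble(
    name   = as.character(name),
    sigma  = if (is.null(sigma)) NA_real_ else sigma,
    b      = b,
    a_attr = if (is.null(a_attr)) NA_real_ else a_attr,
    mass   = if (is.null(mass)) NA_real_ else mass
  )
  class(out) <- c("vdw_species", class(out))
  out
}

#' Molar volume at temperature under constant expansivity
#'
#' Integrates `d ln v / dT = alpha_P` with a temperature-independent
#' isobaric expansion coefficient, giving the exact exponential
#' `v(T) = v_ref * exp(alpha_P * (T - T_ref))`. This is the temperature
#' model behind every analytic temperature derivative in the package:
#' with it, the closed-form entropies and enthalpies are the exact
#' derivatives of the free energies.
#'
#' @param v1_ref Molar volume at `T_ref`, cm^3 mol^-1 (> 0).
#' @param alpha_P Isobaric thermal expansion coefficient, K^-1.
#' @param T_ref Reference temperature, K.
#' @param T Target temperature(s), K (> 0).
#' @return Molar volume(s) at `T`, cm^3 mol^-1.
#' @export
#' @examples
#' molar_volume_at_T(18.07, 0.257e-3, 298.15, 310)
molar_volume_at_T <- function(v1_ref, alpha_P, T_ref, T) {
  if (any(v1_ref <= 0)) {
    abort("`v1_ref` must be positive.", class = "vdwsolv_domain_error")
  }
  if (any(T <= 0)) abort("`T` must be positive.", class = "vdwsolv_domain_error")
  v1_ref * exp(alpha_P * (T - T_ref))
}

# Shared input checks for solvent tables. Requires columns v1 and alpha_P
# plus either sigma or b1; returns the table with a `b1` column filled via
# the packing convention and a `name` column.
validate_solvents <- function(solvents, call = rlang::caller_env()) {
  if (!is.data.frame(solvents)) {
    abort("`solvents` must be a data frame.", class = "vdwsolv_domain_error",
          call = call)
  }
  d <- as_tibble(solvents)
  if (!"v1" %in% names(d) || !"alpha_P" %in% names(d)) {
    abort("`solvents` needs columns `v1` (cm^3/mol) and `alpha_P` (K^-1).",
          class = "vdwsolv_domain_error", call = call)
  }
  if (!"name" %in% names(d)) d$name <- paste0("solvent", seq_len(nrow(d)))
  if (!"b1" %in% names(d)) {
    if (!"sigma" %in% names(d)) {
      abort("`solvents` needs a `sigma` (A) or `b1` (A^3) column.",
            class = "vdwsolv_domain_error", call = call)
    }
    d$b1 <- hard_sphere_b(d$sigma)
  }
  if (any(d$v1 <= 0)) {
    abort("All molar volumes `v1` must be positive.",
          class = "vdwsolv_domain_error", call = call)
  }
  if (any(d$alpha_P < 0)) {
    warn("Negative `alpha_P` supplied (e.g. water below 4 degC); formulas remain valid.")
  }
  d
}
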