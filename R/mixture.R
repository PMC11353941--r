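#' Finite-composition van der Waals binary mixture
#'
#' Builds the state of a binary solution of monoatomic van der Waals
#' fluids in per-molecule units: particle counts `N1`, `N2` (continuous
#' non-negative reals, so that composition derivatives are well defined),
#' volume `V` in A^3, repulsive volumes `b1`, `b2` in A^3, attraction
#' parameters `a1`, `a2` in J A^3 per molecule pair (see
#' [a_molar_to_molecular()]), and optional molecular masses in kg (needed
#' only for absolute translational free energies; when missing, thermal
#' de Broglie wavelengths are taken as 1 A and the ideal part is purely
#' configurational).
#'
#' @param b1,b2 Repulsive volume parameters, A^3 (non-negative).
#' @param a1,a2 Attraction parameters, J A^3 (non-negative).
#' @param N1,N2 Particle numbers (non-negative, not both zero).
#' @param V System volume, A^3; must exceed `b1*N1 + b2*N2`.
#' @param T Temperature, K.
#' @param m1,m2 Molecular masses, kg, or `NULL`.
#' @return A list of class `vdw_mixture`.
#' @export
#' @examples
#' mixture_state(b1 = 18, b2 = 52.4, a1 = 0, a2 = 0,
#'               N1 = 100, N2 = 1, V = 4000, T = 298.15)
mixture_state <- function(b1, b2, a1, a2, N1, N2, V, T,
                          m1 = NULL, m2 = NULL) {
  if (any(c(b1, b2, a1, a2) < 0)) {
    abort("`b` and `a` parameters must be non-negative.",
          class = "vdwsolv_domain_error")
  }
  if (N1 < 0 || N2 < 0 || (N1 == 0 && N2 == 0)) {
    abort("Need N1 >= 0, N2 >= 0 and not both zero.",
          class = "vdwsolv_domain_error")
  }
  if (T <= 0) abort("`T` must be positive.", class = "vdwsolv_domain_error")
  if (V <= b1 * N1 + b2 * N2) {
    abort(sprintf(
      "Overpacked mixture: V = %.6g <= b1*N1 + b2*N2 = %.6g A^3 (no free volume).",
      V, b1 * N1 + b2 * N2), class = "vdwsolv_overpacked_error")
  }
  structure(list(b1 = b1, b2 = b2, a1 = a1, a2 = a2,
                 N1 = N1, N2 = N2, V = V, T = T, m1 = m1, m2 = m2),
            class = "vdw_mixture")
}

# thermal de Broglie wavelength in A; 1 A when mass is unknown
lambda_A <- function(mass, T) {
  if (is.null(mass)) return(1)
  .const$h / sqrt(2 * pi * mass * .const$kB * T) * 1e10
}

#' Helmholtz free energy of a van der Waals binary mixture
#'
#' `A = -kT ln Q` for the classical partition function of the mixture,
#' with Stirling's continuous-N form `ln N! = N ln N - N`. The result is
#' split into an ideal translational/mixing part (the only piece that
#' depends on masses) and an excess part
#' `-kT (N1+N2) ln(Vfree/V) - (sqrt(a1) N1 + sqrt(a2) N2)^2 / V`,
#' where `Vfree = V - b1 N1 - b2 N2`. The attractive potential energy of
#' the mixture is exactly the second term.
#'
#' @param state A [mixture_state()].
#' @return A list with components `total`, `ideal`, `excess` and
#'   `attractive` (all J for the whole system).
#' @export
#' @examples
#' s <- mixture_state(18, 52.4, 0, 0, 100, 1, 6000, 298.15)
#' helmholtz_energy(s)$excess
helmholtz_energy <- function(state) {
  stopifnot(inherits(state, "vdw_mixture"))
  kT <- .const$kB * state$T
  N <- state$N1 + state$N2
  Vfree <- state$V - state$b1 * state$N1 - state$b2 * state$N2
  S <- sqrt(state$a1) * state$N1 + sqrt(state$a2) * state$N2
  attractive <- -S^2 / state$V

  ideal_term <- function(Ni, mi) {
    if (Ni == 0) return(0)
    Ni * (log(Ni * lambda_A(mi, state$T)^3 / state$V) - 1)
  }
  ideal <- kT * (ideal_term(state$N1, state$m1) +
                 ideal_term(state$N2, state$m2))
  excess <- -kT * N * log(Vfree / state$V) + attractive
  list(total = ideal + excess, ideal = ideal, excess = excess,
       attractive = attractive)
}

#' Analytic chemical potential in the van der Waals mixture
#'
#' Differentiating the mixture Helmholtz free energy with respect to the
#' particle number of one component at fixed `T`, `V` and the other
#' count gives, for component 2,
#'
#' \deqn{\mu_2 = kT\ln(\rho_2 \Lambda_2^3) + \mu_2^\bullet}
#' \deqn{\mu_2^\bullet = -kT\ln\frac{V_{free}}{V} + kT\frac{(N_1+N_2) b_2}{V_{free}}
#'   - \frac{2\sqrt{a_2}(\sqrt{a_1}N_1+\sqrt{a_2}N_2)}{V}}
#'
#' `mu_star` is the Ben-Naim standard part — the coupling work of a
#' particle fixed in the solution — and is defined for `N2 = 0`, where it
#' reduces to the infinite-dilution solvation free energy. The
#' translational term requires `N2 > 0` (and a mass for an absolute
#' value). `component = 1` uses the same expression with labels swapped.
#'
#' @param state A [mixture_state()].
#' @param component Which component's chemical potential (1 or 2).
#' @return A list with `mu_star` and `mu_total` (J per molecule;
#'   `mu_total` is `NA` when the component count is zero) plus
#'   `mu_star_kJmol`, the molar equivalent of `mu_star`.
#' @export
#' @examples
#' s <- mixture_state(18, 52.4, 0, 0, 1000, 0, 30000, 298.15)
#' chemical_potential(s)$mu_star_kJmol
chemical_potential <- function(state, component = 2) {
  stopifnot(inherits(state, "vdw_mixture"), component %in% c(1, 2))
  kT <- .const$kB * state$T
  N <- state$N1 + state$N2
  Vfree <- state$V - state$b1 * state$N1 - state$b2 * state$N2
  S <- sqrt(state$a1) * state$N1 + sqrt(state$a2) * state$N2
  if (component == 2) {
    bc <- state$b2; ac <- state$a2; Nc <- state$N2; mc <- state$m2
  } else {
    bc <- state$b1; ac <- state$a1; Nc <- state$N1; mc <- state$m1
  }
  mu_star <- -kT * log(Vfree / state$V) + kT * N * bc / Vfree -
    2 * sqrt(ac) * S / state$V
  mu_total <- if (Nc > 0) {
    kT * log(Nc / state$V * lambda_A(mc, state$T)^3) + mu_star
  } else NA_real_
  list(mu_star = mu_star, mu_total = mu_total,
       mu_star_kJmol = mu_star * .const$N_Av / 1e3)
}

#' Chemical potential by finite differences
#'
#' Central-difference derivative of [helmholtz_energy()] with respect to
#' one particle count at fixed `T`, `V` and the other count — the
#' independent numerical oracle for [chemical_potential()].
#'
#' @param state A [mixture_state()].
#' @param delta Step in particle number; default `1e-6 * (N1 + N2)`.
#'   Must satisfy `0 < delta < Nc`.
#' @param component Which component (1 or 2).
#' @return Derivative in J per molecule.
#' @export
#' @examples
#' s <- mixture_state(18, 52.4, 0, 0, 100, 5, 8000, 298.15)
#' numeric_mu(s) - chemical_potential(s)$mu_total
numeric_mu <- function(state, delta = NULL, component = 2) {
  stopifnot(inherits(state, "vdw_mixture"))
  delta <- delta %||% (1e-6 * (state$N1 + state$N2))
  Nc <- if (component == 2) state$N2 else state$N1
  if (delta <= 0 || Nc - delta <= 0) {
    abort("Finite-difference step must satisfy 0 < delta < Nc.",
          class = "vdwsolv_domain_error")
  }
  shift <- function(h) {
    s <- unclass(state)
    if (component == 2) s$N2 <- s$N2 + h else s$N1 <- s$N1 + h
    helmholtz_energy(do.call(mixture_state, s))$total
  }
  (shift(delta) - shift(-delta)) / (2 * delta)
}

#' van der Waals equation-of-state pressure of the mixture
#'
#' `P = (N1+N2) kT / Vfree - (sqrt(a1) N1 + sqrt(a2) N2)^2 / V^2`,
#' which equals `-dA/dV` of [helmholtz_energy()] at fixed `T`, `N1`, `N2`.
#'
#' @param state A [mixture_state()].
#' @return Pressure in J per A^3 (multiply by 1e30 for Pa).
#' @export
vdw_pressure <- function(state) {
  stopifnot(inherits(state, "vdw_mixture"))
  kT <- .const$kB * state$T
  Vfree <- state$V - state$b1 * state$N1 - state$b2 * state$N2
  S <- sqrt(state$a1) * state$N1 + sqrt(state$a2) * state$N2
  (state$N1 + state$N2) * kT / Vfree - S^2 / state$V^2
}

#' Dilute mixture state from molar solvent properties
#'
#' Convenience constructor bridging the molar solvation calculators and
#' the per-molecule mixture model: a solution of `N` particles at solute
#' mole fraction `x2` in a solvent of molar volume `v1`, with every
#' particle allotted the solvent's molecular volume (`V = N v1 / N_Av`,
#' reducing to `N1 v1 / N_Av` at infinite dilution), and attraction
#' parameters given in molar units.
#'
#' @param v1 Solvent molar volume, cm^3 mol^-1.
#' @param b1,b2 Repulsive volumes, A^3.
#' @param a1_molar,a2_molar Attraction parameters, kJ cm^3 mol^-2.
#' @param x2 Solute mole fraction in `[0, 1)`.
#' @param N Total particle number.
#' @param T Temperature, K.
#' @return A [mixture_state()].
#' @export
#' @examples
#' s <- dilute_mixture_state(18.07, hard_sphere_b(2.8), hard_sphere_b(4),
#'                           0, 0, x2 = 1e-9)
#' chemical_potential(s)$mu_star_kJmol
dilute_mixture_state <- function(v1, b1, b2, a1_molar = 0, a2_molar = 0,
                                 x2 = 0, N = 1e4, T = 298.15) {
  stopifnot(x2 >= 0, x2 < 1, v1 > 0, N > 0)
  N2 <- x2 * N
  N1 <- N - N2
  V <- N * v1 * 1e24 / .const$N_Av
  mixture_state(b1 = b1, b2 = b2,
                a1 = a_molar_to_molecular(a1_molar),
                a2 = a_molar_to_molecular(a2_molar),
                N1 = N1, N2 = N2, V = V, T = T)
}
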