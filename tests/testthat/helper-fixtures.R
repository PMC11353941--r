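# Shared fixtures for the suite. All fixtures are generated in code.

# Water row of the built-in table, as a one-row solvent tibble.
water_row <- function() builtin_solvents()[1, ]

# Random valid mixture states in per-molecule units. Packing (occupied
# volume fraction) is kept in [0.3, 0.8] so every state has free volume.
random_mixture_states <- function(n, seed, with_mass = FALSE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    b1 <- runif(1, 10, 300); b2 <- runif(1, 10, 300)
    N1 <- runif(1, 50, 500); N2 <- runif(1, 1, 100)
    V <- (b1 * N1 + b2 * N2) / runif(1, 0.3, 0.8)
    mixture_state(
      b1 = b1, b2 = b2,
      a1 = a_molar_to_molecular(runif(1, 0, 1e6)),
      a2 = a_molar_to_molecular(runif(1, 0, 1e6)),
      N1 = N1, N2 = N2, V = V, T = runif(1, 250, 400),
      m1 = if (with_mass) runif(1, 2, 200) * 1.66053907e-27 else NULL,
      m2 = if (with_mass) runif(1, 2, 200) * 1.66053907e-27 else NULL
    )
  })
}

# Central finite-difference temperature derivatives of a thermodynamic
# table function f(T) returning a tibble with column `col` (kJ/mol).
# Returns dS = -d(dG)/dT in J/K/mol and dH = -T^2 d(dG/T)/dT in kJ/mol.
fd_temperature_derivatives <- function(f, T, h = 1e-3, col = "dG_c") {
  up <- f(T + h)[[col]]
  dn <- f(T - h)[[col]]
  dS <- -(up - dn) / (2 * h) * 1e3
  dH <- -T^2 * (up / (T + h) - dn / (T - h)) / (2 * h)
  list(dS = dS, dH = dH)
}

expect_rel_equal <- function(actual, expected, tol, scale = NULL) {
  if (is.null(scale)) scale <- pmax(abs(expected), 1e-12)
  expect_true(all(abs(actual - expected) <= tol * scale))
}

temp_csv <- function() tempfile(fileext = ".csv")

`%||%` <- function(a, b) if (is.null(a)) b else a
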