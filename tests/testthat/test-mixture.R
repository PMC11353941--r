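kB <- vdw_constants()$kB

test_that("mixture state validates free volume and composition", {
  expect_error(mixture_state(18, 52, 0, 0, 100, 10, V = 100, T = 298.15),
               class = "vdwsolv_overpacked_error")
  expect_error(mixture_state(18, 52, 0, 0, 0, 0, V = 1e4, T = 298.15),
               class = "vdwsolv_domain_error")
  expect_error(mixture_state(-1, 52, 0, 0, 10, 1, V = 1e4, T = 298.15),
               class = "vdwsolv_domain_error")
})

test_that("ideal-gas and single-component limits are recovered", {
  # no size, no attraction: excess free energy is zero
  st <- mixture_state(0, 0, 0, 0, 200, 50, V = 1e5, T = 300)
  expect_equal(helmholtz_energy(st)$excess, 0)
  expect_equal(chemical_potential(st, 2)$mu_star, 0)
  # with mass, mu2 reduces to the ideal-gas chemical potential kT ln(rho2 L2^3)
  m <- 131.29 * 1.66053907e-27  # xenon, kg
  stm <- mixture_state(0, 0, 0, 0, 200, 50, V = 1e5, T = 300, m2 = m)
  h <- vdw_constants()$h
  L2 <- h / sqrt(2 * pi * m * kB * 300) * 1e10
  expect_rel_equal(chemical_potential(stm, 2)$mu_total,
                   kB * 300 * log(50 / 1e5 * L2^3), tol = 1e-12)
  # N2 = 0: pure fluid 1 with attraction energy -a1 N1^2 / V
  st1 <- mixture_state(18, 52, 3e-21, 5e-21, 300, 0, V = 2e4, T = 298.15)
  expect_rel_equal(helmholtz_energy(st1)$attractive,
                   -3e-21 * 300^2 / 2e4, tol = 1e-12)
})

test_that("the EOS pressure is minus the volume derivative of A", {
  for (st in random_mixture_states(20, seed = 31)) {
    h <- 1e-6 * st$V
    perturb <- function(dV) {
      s <- unclass(st); s$V <- s$V + dV
      helmholtz_energy(do.call(mixture_state, s))$total
    }
    fd <- -(perturb(h) - perturb(-h)) / (2 * h)
    expect_rel_equal(fd, vdw_pressure(st), tol = 1e-6)
  }
})

test_that("analytic chemical potential matches the finite-difference oracle", {
  for (st in random_mixture_states(200, seed = 5)) {
    mu_an <- chemical_potential(st, 2)$mu_total
    mu_fd <- numeric_mu(st, component = 2)
    expect_rel_equal(mu_fd, mu_an, tol = 1e-6,
                     scale = max(abs(mu_an), kB * st$T))
  }
})

test_that("the finite-difference derivative converges at second order", {
  st <- mixture_state(18, 52.4, a_molar_to_molecular(500),
                      a_molar_to_molecular(900), 100, 5, 8000, 298.15)
  exact <- chemical_potential(st, 2)$mu_total
  e1 <- abs(numeric_mu(st, delta = 0.2) - exact)
  e2 <- abs(numeric_mu(st, delta = 0.1) - exact)
  expect_gt(e1 / e2, 3.2)  # ~4x shrink when the step is halved
  expect_lt(e1 / e2, 4.8)
  expect_error(numeric_mu(st, delta = 10), class = "vdwsolv_domain_error")
})

test_that("Gibbs-Duhem: N1 dmu1 + N2 dmu2 tracks V dP at fixed T and V", {
  for (st in random_mixture_states(20, seed = 17)) {
    h <- 1e-6 * (st$N1 + st$N2)
    at_N2 <- function(dN2) {
      s <- unclass(st); s$N2 <- s$N2 + dN2
      do.call(mixture_state, s)
    }
    d_of <- function(f) (f(at_N2(h)) - f(at_N2(-h))) / (2 * h)
    dmu1 <- d_of(function(s) chemical_potential(s, 1)$mu_star)
    dmu2 <- d_of(function(s) chemical_potential(s, 2)$mu_total)
    dP <- d_of(vdw_pressure)
    # the ln rho1 part of mu1_total: d(kT ln N1/V)/dN2 = 0 at fixed N1, V
    lhs <- st$N1 * dmu1 + st$N2 * dmu2
    rhs <- st$V * dP
    expect_lt(abs(lhs - rhs), 1e-5 * max(abs(lhs), abs(rhs), kB * st$T))
  }
})

test_that("infinite-dilution mu2_star equals the closed-form solvation result", {
  solv <- builtin_solvents()
  set.seed(41)
  solv$a_attr <- runif(8, 100, 2000)  # synthetic attraction parameters
  a2 <- 850
  direct <- solvate(solv, a_solute = a2)
  for (i in seq_len(nrow(solv))) {
    st <- dilute_mixture_state(solv$v1[i], solv$b1[i], hard_sphere_b(4),
                               a1_molar = solv$a_attr[i], a2_molar = a2,
                               x2 = 1e-9)
    expect_lt(abs(chemical_potential(st, 2)$mu_star_kJmol -
                    direct$dG_star[i]), 1e-6)
  }
})

test_that("the coupling work depends on composition for unequal species", {
  mu_at <- function(x2) {
    st <- dilute_mixture_state(80, hard_sphere_b(3.8), hard_sphere_b(5),
                               a1_molar = 400, a2_molar = 1200, x2 = x2)
    chemical_potential(st, 2)$mu_star_kJmol
  }
  vals <- vapply(c(1e-9, 0.1, 0.5), mu_at, numeric(1))
  expect_gt(diff(range(vals)), 0.1)  # kJ/mol; far from constant
  # identical species: composition independent
  mu_same <- function(x2) {
    st <- dilute_mixture_state(80, hard_sphere_b(3.8), hard_sphere_b(3.8),
                               a1_molar = 400, a2_molar = 400, x2 = x2)
    chemical_potential(st, 2)$mu_star_kJmol
  }
  same <- vapply(c(1e-9, 0.1, 0.5), mu_same, numeric(1))
  expect_equal(diff(range(same)), 0, tolerance = 1e-9)
})
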