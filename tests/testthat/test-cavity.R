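test_that("cavity thermodynamics reproduces the water and methanol benchmarks", {
  cav <- cavity_thermo(builtin_solvents())
  water <- cav[cav$name == "water", ]
  expect_equal(water$dG_c, 13.0, tolerance = 0.05 / 13)
  expect_equal(water$dH_c, 2.3, tolerance = 0.05 / 2.3)
  expect_equal(water$dS_c, -35.9, tolerance = 0.05 / 35.9)
  meoh <- cav[cav$name == "methanol", ]
  expect_equal(meoh$dG_c, 8.8, tolerance = 0.05 / 8.8)
  expect_equal(meoh$dH_c, 8.5, tolerance = 0.05 / 8.5)
})

test_that("a zero-size system does no cavity work", {
  d <- tibble::tibble(name = "point", sigma = 0, v1 = 50, alpha_P = 1e-3)
  cav <- cavity_thermo(d, b_solute = 0)
  expect_equal(cav$dG_c, 0)
  expect_equal(cav$dH_c, 0)
  expect_equal(cav$dS_c, 0)
})

test_that("overpacked liquids are rejected with the offending packing named", {
  d <- tibble::tibble(name = "dense", sigma = 5,
                      v1 = hard_sphere_b(5) * vdw_constants()$N_Av / 1e24,
                      alpha_P = 1e-3)  # v1 chosen so rho1*b1 = 1
  err <- expect_error(cavity_thermo(d), class = "vdwsolv_overpacked_error")
  expect_match(conditionMessage(err), "rho1\\*b1")
  expect_match(conditionMessage(err), "dense")
})

test_that("thermodynamic identities hold to near machine precision", {
  systems <- simulate_solvent_systems(1000, seed = 11)
  T <- 298.15
  cav <- cavity_thermo(systems, b_solute = 52.4, T = T)
  expect_rel_equal(cav$dG_c, cav$dH_c - T * cav$dS_c / 1e3, tol = 1e-12,
                   scale = pmax(abs(cav$dG_c), abs(cav$dH_c)))
  expect_rel_equal(cav$dS_c, cav$dS_x + cav$dS_nx, tol = 1e-12,
                   scale = pmax(abs(cav$dS_x), abs(cav$dS_nx)))
  expect_equal(cav$dS_x, -cav$dG_c * 1e3 / T)
  expect_equal(cav$dS_nx, cav$dH_c * 1e3 / T)
  expect_true(all(cav$dS_x <= 0))
  # dH_c and dS_nx carry the sign of alpha_P
  expect_true(all(sign(cav$dH_c) == sign(systems$alpha_P) |
                    systems$alpha_P == 0))
})

test_that("cavity work grows with solute size and with solvent packing", {
  solv <- water_row()
  sizes <- seq(0.5, 8, by = 0.5)
  dG <- vapply(sizes,
               function(s) cavity_thermo(solv, sigma_solute = s)$dG_c,
               numeric(1))
  expect_true(all(diff(dG) > 0))

  b1 <- hard_sphere_b(3.5)
  xi <- seq(0.2, 0.9, by = 0.05)
  v1 <- vdw_constants()$N_Av * b1 / (xi * 1e24)
  d <- tibble::tibble(name = sprintf("xi%.2f", xi), sigma = 3.5,
                      v1 = v1, alpha_P = 1e-3)
  dG_xi <- cavity_thermo(d)$dG_c
  expect_true(all(diff(dG_xi) > 0))
})

test_that("structural reorganization is enthalpy-entropy compensating", {
  solv <- water_row()
  base <- cavity_thermo(solv)
  for (f in c(0, 0.5, 2, 10)) {
    mod <- solv
    mod$alpha_P <- mod$alpha_P * f
    cav <- cavity_thermo(mod)
    expect_identical(cav$dG_c, base$dG_c)         # bit-identical in alpha_P
    expect_equal(cav$dH_c, f * base$dH_c)         # linear and homogeneous
    expect_equal(298.15 * cav$dS_nx / 1e3, cav$dH_c)
  }
})

test_that("negative expansivity is accepted with a warning", {
  cold_water <- water_row()
  cold_water$alpha_P <- -0.68e-4  # water near 2 degC expands on cooling
  expect_warning(cav <- cavity_thermo(cold_water), "alpha_P")
  expect_true(cav$dH_c < 0)
  expect_true(cav$dS_nx < 0)
})

test_that("kinetic pressure reproduces the insertion term and is immense in water", {
  v1 <- 18.07
  b1m <- hard_sphere_b(2.80) * vdw_constants()$N_Av / 1e24
  b2m <- hard_sphere_b(4) * vdw_constants()$N_Av / 1e24
  P <- kinetic_pressure(v1, b1m, 298.15)
  expect_gt(P, 1000)  # atm
  # P_kin * b2 equals the second cavity term exactly
  R <- vdw_constants()$R
  pv_work <- P * vdw_constants()$atm_Pa * b2m * 1e-6 / 1e3  # kJ/mol
  expect_equal(pv_work, R * 298.15 * b2m / (v1 - b1m) / 1e3,
               tolerance = 1e-12)
  second_term <- cavity_thermo(water_row())$dG_c -
    (-R * 298.15 * log(1 - b1m / v1) / 1e3)
  expect_equal(pv_work, second_term, tolerance = 1e-10)
  expect_equal(kinetic_pressure(24465.5, 0, 298.15), 1, tolerance = 1e-4)
  expect_error(kinetic_pressure(10, 12), class = "vdwsolv_overpacked_error")
})
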