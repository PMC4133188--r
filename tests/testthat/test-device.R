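geom <- device_geometry()
fl <- fluid_props()

test_that("needle pressure drop matches the hand-evaluated closed form", {
  # viscous 8 mu L Q / (pi r^4) and kinetic alpha rho Q^2 / (2 pi^2 r^4)
  # evaluated independently at Q = 100 uL/s, water, L = 6 mm, r = 66.5 um
  Q <- uL_to_m3(100)
  visc <- 8 * 1e-3 * 6e-3 * Q / (pi * 66.5e-6^4)
  kin <- 2 * 1000 * Q^2 / (2 * pi^2 * 66.5e-6^4)
  expect_equal(visc, 7.81e4, tolerance = 1e-3)
  expect_equal(kin, 5.18e4, tolerance = 1e-3)
  expect_equal(needle_pressure_drop(Q, geom, fl), visc + kin)
  expect_equal(needle_pressure_drop(0, geom, fl), 0)
  expect_error(needle_pressure_drop(-1e-9, geom, fl),
               class = "invalid_input")
})

test_that("doubling Q doubles the viscous and quadruples the kinetic term", {
  Q <- uL_to_m3(80)
  visc_only <- device_geometry(alpha_kinetic = 0)
  v1 <- needle_pressure_drop(Q, visc_only, fl)
  v2 <- needle_pressure_drop(2 * Q, visc_only, fl)
  expect_equal(v2, 2 * v1)
  k1 <- needle_pressure_drop(Q, geom, fl) - v1
  k2 <- needle_pressure_drop(2 * Q, geom, fl) - v2
  expect_equal(k2, 4 * k1)
})

test_that("outlet pressure and spring force are exact algebraic inverses", {
  for (Q in uL_to_m3(c(0, 37, 100, 150))) {
    for (F_spring in c(5, 15, 23.5)) {
      p2 <- outlet_pressure(F_spring, Q, geom, fl)
      expect_equal(spring_force_from_outlet(p2, Q, geom, fl), F_spring,
                   tolerance = 1e-12)
    }
  }
  # static balance
  expect_equal(outlet_pressure(10, 0, geom, fl), 10 / (pi * geom$r_s^2))
  expect_equal(spring_force_from_outlet(101325, 0, geom, fl),
               pi * geom$r_s^2 * 101325)
})

test_that("largest air flow raises the spring force by the needle drop", {
  Q <- uL_to_m3(150)
  F0 <- spring_force_from_outlet(101325, 0, geom, fl)
  F1 <- spring_force_from_outlet(101325, Q, geom, fl)
  expect_equal(F1 - F0, pi * geom$r_s^2 * needle_pressure_drop(Q, geom, fl))
  expect_gt(F1, F0)
})

test_that("needle radius inverts the pressure-drop relation", {
  Q <- uL_to_m3(100)
  dp <- needle_pressure_drop(Q, geom, fl)
  expect_equal(needle_radius_from_flow(dp, Q, geom$L_n, fl), geom$r_n,
               tolerance = 1e-12)
  # scaling law: quadrupling delta_p at fixed Q multiplies r_n by 4^(-1/4)
  expect_equal(needle_radius_from_flow(4 * dp, Q, geom$L_n, fl),
               geom$r_n * 4^(-1 / 4), tolerance = 1e-12)
  # pure Poiseuille limit
  expect_equal(needle_radius_from_flow(dp, Q, geom$L_n, fl,
                                       alpha_kinetic = 0),
               (8 * fl$mu * geom$L_n * Q / (pi * dp))^(1 / 4),
               tolerance = 1e-12)
})

test_that("neglected syringe drop and retained kinetic term are justified", {
  Q <- uL_to_m3(150)
  expect_gt(needle_to_syringe_drop_ratio(Q, geom, fl), 1e3)
  ratio <- kinetic_to_viscous_ratio(Q, geom, fl)
  expect_gt(ratio, 0.1)
  expect_lt(ratio, 10)
})
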