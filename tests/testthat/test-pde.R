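par0 <- tissue_params(k = 1e-10, K = 1e5, phi0 = 0.01)
fl <- fluid_props()

test_that("zero flow stays at equilibrium", {
  g <- radial_grid(1e-4, 50e-3, 100)
  sol <- solve_pressure(par0, 0, fl, g, c(0, 0.5, 1))
  expect_equal(max(abs(sol$p - par0$p0)), 0, tolerance = 1e-6)
  expect_equal(max(abs(sol$p_tip - par0$p0)), 0, tolerance = 1e-6)
  expect_equal(max(abs(darcy_velocity(sol))), 0, tolerance = 1e-12)
  expect_equal(depot_radius(sol, 0.1), g$r_inner)
})

test_that("constant injection is non-increasing in r and non-decreasing in t", {
  g <- radial_grid(1e-4, 50e-3, 150)
  sol <- solve_pressure(par0, uL_to_m3(100), fl, g, seq(0, 2, by = 0.5))
  # radial monotonicity at every output time
  expect_true(all(apply(sol$p, 1, function(p) all(diff(p) <= 1e-6))))
  # temporal monotonicity at every radius (approach to steady state)
  expect_true(all(apply(sol$p, 2, function(p) all(diff(p) >= -1e-6))))
  # outward Darcy velocity everywhere
  expect_true(all(darcy_velocity(sol)[-1, ] >= -1e-12))
})

test_that("solution depends on k and mu only through their ratio", {
  g <- radial_grid(1e-4, 50e-3, 100)
  t_eval <- c(0, 0.5, 1)
  s1 <- solve_pressure(par0, uL_to_m3(100), fl, g, t_eval)
  par_scaled <- tissue_params(k = 3 * par0$k, K = par0$K, phi0 = par0$phi0)
  fl_scaled <- fluid_props(mu = 3 * fl$mu, rho = fl$rho)
  s2 <- solve_pressure(par_scaled, uL_to_m3(100), fl_scaled, g, t_eval)
  expect_equal(s2$p, s1$p, tolerance = 1e-8)
  expect_equal(s2$p_tip, s1$p_tip, tolerance = 1e-8)
})

test_that("grid and tolerance refinement changes the tip trace by < 0.5%", {
  coarse <- solve_pressure(par0, uL_to_m3(100), fl,
                           radial_grid(1e-4, 50e-3, 150), c(0, 1, 2),
                           rtol = 1e-6)
  fine <- solve_pressure(par0, uL_to_m3(100), fl,
                         radial_grid(1e-4, 50e-3, 300), c(0, 1, 2),
                         rtol = 1e-7)
  over_c <- coarse$p_tip[-1] - par0$p0
  over_f <- fine$p_tip[-1] - par0$p0
  expect_lt(max(abs(over_c / over_f - 1)), 0.005)
})

test_that("steady closed form evaluates the documented magnitudes", {
  Q <- uL_to_m3(100)
  expect_equal(steady_state_pressure(par0, Q, fl, 5e-3) - par0$p0,
               1.59e3, tolerance = 5e-3)
  # near the needle the over-pressure reaches the ~800 mbar order the
  # method is designed to resolve
  expect_equal(steady_state_pressure(par0, Q, fl, 1e-4) - par0$p0,
               7.96e4, tolerance = 5e-3)
  expect_equal(steady_state_pressure(par0, Q, fl, 1e9), par0$p0,
               tolerance = 1e-6)
})

test_that("depot radius is exact on an analytic 1/r profile", {
  g <- radial_grid(1e-4, 50e-3, 400)
  sol <- solve_pressure(par0, uL_to_m3(1), fl, g, c(0, 30), linearised = TRUE)
  # small-amplitude long run: quasi-steady 1/r out to several mm
  expect_equal(depot_radius(sol, 0.1), 10 * g$r_inner, tolerance = 0.02)
  expect_equal(depot_radius(sol, 0.999), g$r_inner, tolerance = 0.05)
})

test_that("boundary flux reproduces the injected flow (Darcy at the tip)", {
  g <- radial_grid(1e-4, 50e-3, 300)
  Q <- uL_to_m3(100)
  sol <- solve_pressure(par0, Q, fl, g, c(0, 2))
  u <- darcy_velocity(sol)
  # in the quasi-steady near field, 4 pi r^2 phi u approximates Q
  i <- which(sol$r > 2e-4 & sol$r < 1e-3)
  flux <- 4 * pi * sol$r[i]^2 * sol$phi[2, i] * u[2, i]
  expect_equal(mean(flux / Q), 1, tolerance = 0.05)
})

test_that("mass balance residual stays below 1% on standard runs", {
  g <- radial_grid(1e-4, 50e-3, 200)
  for (Q_uL in c(20, 100)) {
    sol <- solve_pressure(par0, uL_to_m3(Q_uL), fl, g, seq(0, 2, 0.5))
    expect_lt(abs(sol$diagnostics$mass_balance_residual), 0.01)
  }
  # and with a declining flow profile
  sol <- solve_pressure(par0, function(t) uL_to_m3(150 - 30 * t), fl, g,
                        seq(0, 2, 0.5))
  expect_lt(abs(sol$diagnostics$mass_balance_residual), 0.01)
})

test_that("solution exports write the documented long and tip formats", {
  g <- radial_grid(1e-4, 50e-3, 50)
  sol <- solve_pressure(par0, uL_to_m3(50), fl, g, c(0, 0.5))
  long <- withr::local_tempfile(fileext = ".csv")
  tip <- withr::local_tempfile(fileext = ".csv")
  write_pressure_solution(sol, long)
  write_tip_trace(sol, tip)
  df <- read.csv(long)
  expect_named(df, c("t_s", "r_mm", "p_Pa", "phi"))
  expect_equal(nrow(df), length(sol$t) * length(sol$r))
  dft <- read.csv(tip)
  expect_named(dft, c("t_s", "p_tip_Pa"))
  expect_equal(dft$p_tip_Pa, sol$p_tip)
})

test_that("invalid grids and inputs are rejected", {
  expect_error(radial_grid(0), class = "invalid_input")
  expect_error(radial_grid(1e-3, 5e-2), class = "invalid_input")  # < 100x
  expect_error(tissue_params(k = -1, K = 1e5), class = "invalid_input")
  expect_error(tissue_params(k = 1e-10, K = 1e5, phi0 = 1.2),
               class = "invalid_input")
  g <- radial_grid(1e-4, 50e-3, 50)
  expect_error(solve_pressure(par0, uL_to_m3(100), fl, g, c(0.5, 1)),
               class = "invalid_input")
  expect_error(solve_pressure(par0, -1e-9, fl, g, c(0, 1)),
               class = "invalid_input")
})
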