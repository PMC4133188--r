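geom <- device_geometry()
fl <- fluid_props()

test_that("air injection with a constant spring gives the constant balance flow", {
  F_const <- 23
  spring <- spring_curve(uL_to_m3(c(0, 300)), c(F_const, F_const))
  sim <- simulate_injection(spring, "air", geom, fl, uL_to_m3(100),
                            jitter_sd = 0)
  # independent scalar root of F/(pi r_s^2) = p_ref + dp(Q)
  drive <- F_const / (pi * geom$r_s^2) - 101325
  Q_ref <- uniroot(function(Q) needle_pressure_drop(Q, geom, fl) - drive,
                   c(1e-12, 1e-5), tol = 1e-18)$root
  expect_equal(max(abs(sim$flow$Q / Q_ref - 1)), 0, tolerance = 1e-9)
})

test_that("dose arithmetic: 240 uL at 10 uL/click is exactly 24 clicks", {
  sub <- pp_test_subject()
  expect_length(sub$air$clicks$times, 24)
  expect_equal(sub$air$delivered, uL_to_m3(240), tolerance = 1e-3)
  expect_false(sub$air$stalled)
})

test_that("tissue always slows the clicks relative to air at equal spring", {
  sub <- pp_test_subject()
  dt_air <- diff(sub$air$clicks_true$times)
  dt_tis <- diff(sub$tissue$clicks_true$times)
  expect_true(all(dt_tis >= dt_air))
  expect_true(all(sub$tissue$tip_pressure$counter_pressure > 0))
})

test_that("air flow decelerates monotonically for a monotone spring", {
  sub <- pp_test_subject()
  expect_true(all(diff(sub$air$flow$Q) < 0))
})

test_that("jitter-free clicks invert to the simulated flow within 0.5%", {
  sub <- pp_test_subject()
  q_mid <- approx(sub$air$Q_trace$t, sub$air$Q_trace$Q,
                  sub$air$flow$t_mid, rule = 2)$y
  expect_lt(max(abs(sub$air$flow$Q / q_mid - 1)), 0.005)
})

test_that("an insufficient spring stalls the injection with a partial dose", {
  weak <- spring_curve(uL_to_m3(c(0, 300)), c(7.3, 7.3))  # barely above p_ref
  sim <- simulate_injection(weak, tissue_params(1e-12, 1e5), geom, fl,
                            uL_to_m3(100), jitter_sd = 0)
  expect_true(sim$stalled)
  expect_lt(sim$delivered, uL_to_m3(100))
})

test_that("cohorts are reproducible and respect the dose grid", {
  c1 <- make_cohort(n_subjects = 2, seed = 9, grid_n = 60)
  c2 <- make_cohort(n_subjects = 2, seed = 9, grid_n = 60)
  expect_identical(c1, c2)
  for (s in c1) {
    dose_uL <- m3_to_uL(s$tissue$dose)
    expect_equal(dose_uL %% 10, 0, tolerance = 1e-9)
    expect_gte(dose_uL, 180 - 1e-9)
    expect_lte(dose_uL, 480 + 1e-9)
    expect_identical(length(s$air), 2L)
    expect_gte(s$truth$k, 1e-11); expect_lte(s$truth$k, 1e-10)
    expect_gte(s$truth$K, 3e4); expect_lte(s$truth$K, 3e5)
  }
})

test_that("the optional slow tail exercises the truncation diagnostic", {
  spring <- pp_test_spring()
  sim <- simulate_injection(spring, "air", geom, fl, uL_to_m3(100),
                            jitter_sd = 0, append_tail_slow = TRUE)
  expect_length(sim$clicks$times, 12)  # 10 dose clicks + 2 slow tail
  expect_identical(suggest_truncation(sim$clicks), 2L)
})
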