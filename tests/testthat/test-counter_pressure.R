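test_that("identical air and tissue flows give exactly zero counter pressure", {
  sub <- pp_test_subject()
  cal <- calibrate_spring(sub$air$flow, sub$geom, sub$fluid)
  ser <- tissue_pressure_series(cal, sub$air$flow, sub$geom, sub$fluid)
  # calibration defines F so that p2 = p_ref at the air flow; feeding the
  # same flow back must return p_ref identically
  expect_equal(max(abs(ser$counter_pressure)), 0, tolerance = 1e-6)
  expect_equal(mean_counter_pressure(ser), 0, tolerance = 1e-6)
})

test_that("recovered tissue pressure matches the simulated tip pressure", {
  sub <- pp_test_subject()
  cal <- calibrate_spring(sub$air$flow, sub$geom, sub$fluid)
  ser <- tissue_pressure_series(cal, sub$tissue$flow, sub$geom, sub$fluid)
  truth_cp <- sub$tissue$tip_pressure$counter_pressure
  expect_lt(max(abs(ser$counter_pressure / truth_cp - 1)), 0.02)
})

test_that("lower tissue flow at equal volume means positive counter pressure", {
  sub <- pp_test_subject()
  cal <- calibrate_spring(sub$air$flow, sub$geom, sub$fluid)
  slow <- sub$air$flow
  slow$Q <- slow$Q * 0.9
  ser <- tissue_pressure_series(cal, slow, sub$geom, sub$fluid)
  expect_true(all(ser$counter_pressure > 0))
  # monotone: slower still -> higher counter pressure
  slower <- sub$air$flow
  slower$Q <- slower$Q * 0.8
  ser2 <- tissue_pressure_series(cal, slower, sub$geom, sub$fluid)
  expect_true(all(ser2$counter_pressure > ser$counter_pressure))
})

test_that("cohort box statistics follow the notched box-plot conventions", {
  kPa <- 1000
  st <- cohort_boxstats(c(1, 2, 3, 4, 5) * kPa, detection_floor = 0)
  expect_equal(st$median, 3 * kPa)
  expect_equal(st$q1, 2 * kPa)
  expect_equal(st$q3, 4 * kPa)
  expect_equal(st$whisker_low, 1 * kPa)
  expect_equal(st$whisker_high, 5 * kPa)
  # notch = median +/- 1.57 IQR / sqrt(n), by hand: 3 +/- 1.404 kPa
  expect_equal(st$notch_low, 3 * kPa - 1.57 * 2 * kPa / sqrt(5))
  expect_equal(st$notch_high, 3 * kPa + 1.404 * kPa, tolerance = 1e-3)
  expect_identical(st$n_included, 5L)
})

test_that("the detection floor excludes low-resistance subjects", {
  st <- cohort_boxstats(c(0, 0, 5000), detection_floor = 500)
  expect_identical(st$n_included, 1L)
  expect_identical(st$n_excluded, 2L)
  expect_equal(st$median, 5000)
  expect_equal(st$notch_high, st$notch_low)  # zero-width notch for n = 1
  all_out <- cohort_boxstats(c(0, 100), detection_floor = 500)
  expect_identical(all_out$n_included, 0L)
  expect_true(is.na(all_out$median))
})

test_that("pressure series export writes the documented columns", {
  sub <- pp_test_subject()
  cal <- calibrate_spring(sub$air$flow, sub$geom, sub$fluid)
  ser <- tissue_pressure_series(cal, sub$tissue$flow, sub$geom, sub$fluid)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pressure_series(ser, path)
  df <- read.csv(path)
  expect_named(df, c("subject_id", "t_mid_s", "V_mid_uL", "p2_Pa",
                     "counter_pressure_mbar"))
  expect_equal(df$counter_pressure_mbar, Pa_to_mbar(ser$counter_pressure))
})
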