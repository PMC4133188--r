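test_that("noise-free synthetic parameters are recovered accurately", {
  sub <- pp_test_subject()
  cal <- calibrate_spring(sub$air$flow, sub$geom, sub$fluid)
  ser <- tissue_pressure_series(cal, sub$tissue$flow, sub$geom, sub$fluid)
  fit <- fit_tissue_params(ser, sub$tissue$flow, sub$geom, sub$fluid)
  expect_true(fit$converged)
  expect_false(any(fit$bounds_hit))
  expect_lt(abs(fit$k_hat / sub$truth$k - 1), 0.05)
  expect_lt(abs(fit$K_hat / sub$truth$K - 1), 0.05)
  expect_lt(fit$sse / fit$n_points, 100)  # residual RMS well under 10 Pa
})

test_that("the optimum is insensitive to a perturbed start (x3 either way)", {
  sub <- pp_test_subject()
  cal <- calibrate_spring(sub$air$flow, sub$geom, sub$fluid)
  ser <- tissue_pressure_series(cal, sub$tissue$flow, sub$geom, sub$fluid)
  f0 <- fit_tissue_params(ser, sub$tissue$flow, sub$geom, sub$fluid)
  f_up <- fit_tissue_params(ser, sub$tissue$flow, sub$geom, sub$fluid,
                            init = c(3e-11, 3e5))
  f_dn <- fit_tissue_params(ser, sub$tissue$flow, sub$geom, sub$fluid,
                            init = c(3e-12, 3.3e4))
  # same optimum: parameters agree within 1%, residuals at the same
  # sub-Pa floor (sse within 1% of each other relative to one data point's
  # worth of 1 Pa^2)
  for (f in list(f_up, f_dn)) {
    expect_lt(abs(f$k_hat / f0$k_hat - 1), 0.01)
    expect_lt(abs(f$K_hat / f0$K_hat - 1), 0.01)
    expect_lt(abs(f$sse - f0$sse), 0.01 * max(f0$sse, f0$n_points))
  }
})

test_that("zero counter pressure pushes the fit to the high-permeability bound", {
  sub <- pp_test_subject()
  cal <- calibrate_spring(sub$air$flow, sub$geom, sub$fluid)
  # feeding the air flow back: measured pressure identically p_ref
  ser <- tissue_pressure_series(cal, sub$air$flow, sub$geom, sub$fluid)
  fit <- fit_tissue_params(ser, sub$air$flow, sub$geom, sub$fluid,
                           control = list(maxit = 150))
  expect_true(fit$bounds_hit[["k"]])
  expect_gt(fit$k_hat, 1e-9)
})

test_that("mismatched grids and out-of-bounds starts are rejected", {
  sub <- pp_test_subject()
  cal <- calibrate_spring(sub$air$flow, sub$geom, sub$fluid)
  ser <- tissue_pressure_series(cal, sub$tissue$flow, sub$geom, sub$fluid)
  expect_error(fit_tissue_params(ser, sub$air$flow, sub$geom, sub$fluid),
               class = "invalid_input")
  expect_error(fit_tissue_params(ser, sub$tissue$flow, sub$geom, sub$fluid,
                                 init = c(1e-20, 1e5)),
               class = "invalid_input")
})
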