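test_that("flow from uniform clicks is uniform and volume-conserving", {
  tr <- click_train(c(0, 0.1, 0.2, 0.3), uL_to_m3(10))
  fl <- flow_from_clicks(tr, truncate_tail = 0)
  expect_equal(fl$Q, rep(uL_to_m3(100), 3))
  expect_equal(fl$t_mid, c(0.05, 0.15, 0.25))
  # click i completes increment i: midpoints at 1.5, 2.5, 3.5 increments
  expect_equal(fl$V_mid, uL_to_m3(c(15, 25, 35)))
  # volume conservation: sum Q dt = retained intervals * vpc
  expect_equal(sum(fl$Q * diff(tr$times)), 3 * uL_to_m3(10))
})

test_that("a 240 uL dose at 10 uL/click yields 24 clicks and 23 intervals", {
  sub <- pp_test_subject()
  expect_length(sub$air$clicks$times, 24)
  expect_equal(nrow(flow_from_clicks(sub$air$clicks, 0)), 23)
  expect_equal(nrow(flow_from_clicks(sub$air$clicks, 2)), 21)
})

test_that("invalid trains are rejected with classed errors", {
  expect_error(click_train(c(0, 0.1, 0.1)), class = "invalid_input")
  expect_error(click_train(c(0, 0.2, 0.1)), class = "invalid_input")
  expect_error(click_train(c(0, NA, 0.2)), class = "invalid_input")
  expect_error(click_train(c(0, 0.1), volume_per_click = 0),
               class = "invalid_input")
  tr <- click_train(c(0, 0.1, 0.2))
  expect_error(flow_from_clicks(tr, truncate_tail = 2),
               class = "insufficient_data")
})

test_that("flow is scale-equivariant in the inter-click intervals", {
  base <- cumsum(c(0, 0.08, 0.09, 0.11, 0.1, 0.12))
  for (c_fac in c(0.5, 2, 3.7)) {
    f1 <- flow_from_clicks(click_train(base), 0)
    f2 <- flow_from_clicks(click_train(base * c_fac), 0)
    expect_equal(f2$Q, f1$Q / c_fac, tolerance = 1e-12)
  }
})

test_that("click tables round-trip and enforce their format", {
  tr <- pp_test_subject()$air$clicks
  path <- withr::local_tempfile(fileext = ".csv")
  write_click_table(tr, path)
  tr2 <- read_click_table(path)
  expect_equal(tr2$times, tr$times)
  expect_equal(tr2$medium, "air")

  # shuffled click_index but sorted times: accepted and re-indexed
  df <- read.csv(path)
  df$click_index <- rev(df$click_index)
  write.csv(df, path, row.names = FALSE)
  expect_equal(read_click_table(path)$times, tr$times)

  # unknown medium and missing columns are format errors
  df$medium <- "water"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_click_table(path), class = "format_error")
  write.csv(df[, c("subject_id", "time_s")], path, row.names = FALSE)
  expect_error(read_click_table(path), class = "format_error")
})

test_that("tail-drop diagnostic flags slow trailing clicks, never applies them", {
  sub <- pp_test_subject()
  tr <- sub$air$clicks
  expect_identical(suggest_truncation(tr), 0L)
  slow <- click_train(c(tr$times,
                        max(tr$times) + 0.3, max(tr$times) + 0.7),
                      tr$volume_per_click)
  expect_identical(suggest_truncation(slow), 2L)
  # the flow series itself is untouched by the diagnostic
  expect_equal(nrow(flow_from_clicks(slow, 0)), length(slow$times) - 1)
})
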