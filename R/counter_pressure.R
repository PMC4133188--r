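#' Tissue pressure series from a calibrated spring and a tissue flow
#'
#' The non-invasive measurement: with the spring force known as a function
#' of delivered volume from the air references, every tissue flow interval
#' gives the needle-outlet pressure through the device balance,
#' `p2(V) = F(V)/(pi r_s^2) - needle_pressure_drop(Q(V))`.  Air and tissue
#' injections are aligned on the delivered-volume coordinate, because the
#' spring state depends on piston position, not on time.  The counter
#' pressure is `p2 - p_ref`.
#'
#' Timing noise on the click times biases the flow and, through the convex
#' needle-drop law, the outlet pressure: with white jitter of SD
#' `timing_sd` on each click time, `E[1/dt] > 1/dt` (so the flow estimate
#' is inflated by `rho = 2 timing_sd^2 / dt^2`) and `E[dp(Q)] > dp(E[Q])`.
#' Both effects push the apparent outlet pressure down, most strongly in
#' the short early intervals.  The series applies the second-order
#' errors-in-variables correction for this known bias; by default the
#' timing scale is estimated from the intervals themselves
#' ([estimate_timing_sd()]), so the correction vanishes for clean data.
#'
#' @param spring a [spring_curve()] calibrated with [calibrate_spring()]
#'   (same `p_ref` convention as used here).
#' @param tissue_flow a `flow_series` measured in tissue.
#' @param geom a [device_geometry()].
#' @param fluid a [fluid_props()].
#' @param p_ref reference pressure, Pa (default 101325).
#' @param timing_sd click-timing noise SD in seconds used for the bias
#'   correction; `NULL` (default) estimates it from the flow series, 0
#'   disables the correction.
#' @return a `pressure_series`: data frame with `t_mid` (s), `V_mid` (m^3),
#'   `p2` (Pa, absolute in the calibration convention) and
#'   `counter_pressure` (Pa, gauge), with `subject_id` and `timing_sd`
#'   attributes.
#' @export
tissue_pressure_series <- function(spring, tissue_flow, geom, fluid,
                                   p_ref = 101325, timing_sd = NULL) {
  stopifnot(inherits(spring, "spring_curve"),
            inherits(tissue_flow, "flow_series"))
  if (nrow(tissue_flow) < 1)
    pp_stop("insufficient_data", "empty tissue flow series")
  if (is.null(timing_sd)) timing_sd <- estimate_timing_sd(tissue_flow)
  spring_covers(spring, tissue_flow)
  F_V <- spring_force(spring, tissue_flow$V_mid, warn_extrapolate = FALSE)
  Q <- tissue_flow$Q
  dt <- attr(tissue_flow, "volume_per_click") / Q
  p2 <- outlet_pressure(F_V, Q, geom, fluid) +
    pp_needle_drop_bias(Q, dt, timing_sd, geom, fluid)
  structure(data.frame(
    t_mid = tissue_flow$t_mid,
    V_mid = tissue_flow$V_mid,
    p2 = p2,
    counter_pressure = p2 - p_ref
  ),
  class = c("pressure_series", "data.frame"),
  subject_id = attr(tissue_flow, "subject_id"),
  p_ref = p_ref,
  timing_sd = timing_sd)
}

#' Estimate the click-timing noise scale from a flow series
#'
#' Inter-click intervals vary smoothly through the injection (the spring
#' untwists, the tissue pressurises), while detection/microphone timing
#' error adds white noise to each click time — i.e. an anticorrelated
#' roughness of variance `2 sd^2` on the intervals.  The roughness is
#' isolated by detrending the intervals with a low-degree smooth and the
#' residual SD is divided by `sqrt(2)`.  Returns 0 for series too short to
#' detrend (< 8 intervals) and for effectively clean series.
#'
#' @param flow a `flow_series` (or a [click_train()]).
#' @return estimated timing SD in seconds.
#' @export
estimate_timing_sd <- function(flow) {
  dt <- if (inherits(flow, "click_train")) diff(flow$times)
        else attr(flow, "volume_per_click") / flow$Q
  n <- length(dt)
  if (n < 8) return(0)
  i <- seq_len(n)
  trend <- stats::smooth.spline(i, dt, df = min(5, n - 3))
  resid <- dt - stats::predict(trend, i)$y
  max(0, stats::sd(resid)) / sqrt(2)
}

#' Mean counter pressure of one injection
#'
#' Unweighted mean of the counter pressure over the retained intervals.
#' Because every interval delivers the same volume increment, this equals
#' the volume-weighted mean.  A subject whose mean is not positive is the
#' degenerate "no flow change" case (low tissue resistance) and will be
#' excluded by the cohort detection floor.
#'
#' @param series a `pressure_series` from [tissue_pressure_series()].
#' @return mean counter pressure in Pa.
#' @export
mean_counter_pressure <- function(series) {
  stopifnot(inherits(series, "pressure_series"))
  if (nrow(series) < 1)
    pp_stop("insufficient_data", "empty pressure series")
  mean(series$counter_pressure)
}

#' Cohort box-plot statistics for per-subject counter pressures
#'
#' Subjects whose mean counter pressure falls below the detection floor are
#' excluded (and counted): a flow change too small to distinguish from the
#' ~2 % flow-measurement uncertainty indicates tissue resistance below what
#' the method can resolve.  For the included values: quartiles by linear
#' interpolation of order statistics (type 7), whiskers at the extreme
#' values, and the notch — an approximate 95 % confidence interval for the
#' median — at `median +/- 1.57 * IQR / sqrt(n)`.
#'
#' @param values per-subject mean counter pressures, Pa.
#' @param detection_floor exclusion threshold, Pa (default 1000 Pa =
#'   10 mbar).
#' @return a `cohort_stats` list: `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `notch_low`, `notch_high` (Pa), `n_included`,
#'   `n_excluded`, and the included `values`.
#' @export
cohort_boxstats <- function(values, detection_floor = 1000) {
  values <- as.numeric(values)
  if (length(values) < 1)
    pp_stop("insufficient_data", "need at least one value")
  inc <- values[values >= detection_floor]
  n <- length(inc)
  if (n == 0) {
    return(structure(list(
      median = NA_real_, q1 = NA_real_, q3 = NA_real_,
      whisker_low = NA_real_, whisker_high = NA_real_,
      notch_low = NA_real_, notch_high = NA_real_,
      n_included = 0L, n_excluded = length(values), values = numeric(0)
    ), class = "cohort_stats"))
  }
  qs <- quantile(inc, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3] - qs[1]
  half_notch <- 1.57 * iqr / sqrt(n)
  structure(list(
    median = qs[2], q1 = qs[1], q3 = qs[3],
    whisker_low = min(inc), whisker_high = max(inc),
    notch_low = qs[2] - half_notch, notch_high = qs[2] + half_notch,
    n_included = n, n_excluded = length(values) - n, values = inc
  ), class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  if (x$n_included == 0) {
    cat(sprintf("<cohort_stats> all %d subjects below detection floor\n",
                x$n_excluded))
    return(invisible(x))
  }
  cat(sprintf(paste0(
    "<cohort_stats> n = %d included, %d excluded\n",
    "  median %.1f mbar (notch %.1f..%.1f), quartiles %.1f..%.1f,",
    " whiskers %.1f..%.1f\n"),
    x$n_included, x$n_excluded,
    Pa_to_mbar(x$median), Pa_to_mbar(x$notch_low), Pa_to_mbar(x$notch_high),
    Pa_to_mbar(x$q1), Pa_to_mbar(x$q3),
    Pa_to_mbar(x$whisker_low), Pa_to_mbar(x$whisker_high)))
  invisible(x)
}

#' Export a per-subject pressure series as CSV
#'
#' Columns: `subject_id`, `t_mid_s`, `V_mid_uL`, `p2_Pa`,
#' `counter_pressure_mbar`.
#'
#' @param series a `pressure_series`.
#' @param path file path.
#' @export
write_pressure_series <- function(series, path) {
  df <- data.frame(
    subject_id = attr(series, "subject_id"),
    t_mid_s = series$t_mid,
    V_mid_uL = m3_to_uL(series$V_mid),
    p2_Pa = series$p2,
    counter_pressure_mbar = Pa_to_mbar(series$counter_pressure)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Notched box plot of cohort counter pressures
#'
#' @param stats a `cohort_stats`.
#' @param path optional PNG path; if `NULL`, draws on the active device.
#' @param ylab axis label.
#' @return `stats`, invisibly.
#' @export
plot_cohort <- function(stats, path = NULL,
                        ylab = "mean counter pressure [mbar]") {
  stopifnot(inherits(stats, "cohort_stats"))
  if (!is.null(path)) {
    grDevices::png(path, width = 480, height = 560)
    on.exit(grDevices::dev.off())
  }
  if (stats$n_included == 0) {
    graphics::plot.new()
    graphics::title(main = "all subjects below detection floor")
    return(invisible(stats))
  }
  suppressWarnings(  # small n: notch may exceed the hinges, still drawn
    graphics::boxplot(Pa_to_mbar(stats$values), notch = stats$n_included > 1,
                      range = 0, ylab = ylab,
                      main = sprintf("cohort counter pressure (n = %d)",
                                     stats$n_included)))
  invisible(stats)
}
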