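#' Spring curves
#'
#' The torsion spring's force on the piston depends only on the piston
#' position, i.e. on the delivered volume `d = V / (pi r_s^2)`.  A
#' `spring_curve` stores the force at a grid of delivered volumes and
#' evaluates by linear interpolation, with flat extrapolation (and a
#' warning) outside the calibrated range.  Piston friction is absorbed into
#' the calibrated force, assuming it does not depend on the flow rate.
#'
#' @param V_knots delivered-volume grid, m^3, strictly increasing.
#' @param F_knots spring force at each knot, N, non-negative.
#' @return a `spring_curve`.
#' @export
spring_curve <- function(V_knots, F_knots) {
  if (length(V_knots) != length(F_knots) || length(V_knots) < 1)
    pp_stop("invalid_input", "V_knots and F_knots must be equal-length, non-empty")
  if (length(V_knots) >= 2 && any(diff(V_knots) <= 0))
    pp_stop("invalid_input", "V_knots must be strictly increasing")
  if (any(F_knots < 0))
    pp_stop("invalid_input", "F_knots must be non-negative")
  structure(list(V_knots = as.numeric(V_knots),
                 F_knots = as.numeric(F_knots)),
            class = "spring_curve")
}

#' @export
print.spring_curve <- function(x, ...) {
  cat(sprintf("<spring_curve> %d knots, V %.0f..%.0f uL, F %.2f..%.2f N\n",
              length(x$V_knots), m3_to_uL(min(x$V_knots)),
              m3_to_uL(max(x$V_knots)), min(x$F_knots), max(x$F_knots)))
  invisible(x)
}

#' Evaluate a spring curve
#'
#' @param spring a [spring_curve()].
#' @param V delivered volumes, m^3.
#' @param warn_extrapolate warn when `V` leaves the calibrated range.
#' @return spring force in N (flat extrapolation outside the knot range).
#' @export
spring_force <- function(spring, V, warn_extrapolate = TRUE) {
  stopifnot(inherits(spring, "spring_curve"))
  rng <- range(spring$V_knots)
  if (warn_extrapolate && any(V < rng[1] - 1e-15 | V > rng[2] + 1e-15))
    pp_warn("spring_extrapolation",
            "evaluating spring curve outside its calibrated volume range")
  if (length(spring$V_knots) == 1) return(rep(spring$F_knots, length(V)))
  approx(spring$V_knots, spring$F_knots, xout = V, rule = 2)$y
}

#' Calibrate the spring curve from air injections
#'
#' During an injection in air the outlet pressure is the known reference
#' pressure, so each flow interval yields the spring force directly:
#' `F(V_mid) = pi r_s^2 (p_ref + needle_pressure_drop(Q))`.  Intervals from
#' all supplied air series (typically one before and one after the tissue
#' injection) are pooled on the shared delivered-volume grid by averaging,
#' and the pooled curve is projected onto non-increasing curves by isotonic
#' least squares — the spring only untwists, so its force cannot grow with
#' delivered volume.
#'
#' Click-timing noise inflates the apparent flow and, through the convex
#' needle-drop law, the apparent force (see [tissue_pressure_series()]);
#' the same second-order correction is subtracted here, with the timing
#' scale estimated per series unless given, so the bias cancels between
#' calibration and tissue read-out.
#'
#' @param air_flows a `flow_series` or list of them, all medium `"air"`,
#'   from the same pen.
#' @param geom a [device_geometry()].
#' @param fluid a [fluid_props()].
#' @param p_ref reference (atmospheric) pressure in Pa; default 101325.
#'   Use 0 for a gauge-calibrated curve.
#' @param timing_sd click-timing noise SD (s) for the bias correction;
#'   `NULL` (default) estimates it per series, 0 disables it.
#' @return a [spring_curve()] with knots on the volume-midpoint grid.
#' @export
calibrate_spring <- function(air_flows, geom, fluid, p_ref = 101325,
                             timing_sd = NULL) {
  if (inherits(air_flows, "flow_series")) air_flows <- list(air_flows)
  if (length(air_flows) < 1)
    pp_stop("insufficient_data", "need at least one air flow series")
  vpc <- attr(air_flows[[1]], "volume_per_click")
  V_all <- unlist(lapply(air_flows, `[[`, "V_mid"))
  F_all <- unlist(lapply(air_flows, function(fl) {
    sd_t <- if (is.null(timing_sd)) estimate_timing_sd(fl) else timing_sd
    spring_force_from_outlet(p_ref, fl$Q, geom, fluid) -
      pi * geom$r_s^2 *
        pp_needle_drop_bias(fl$Q, vpc / fl$Q, sd_t, geom, fluid)
  }))
  # pool on the shared half-increment grid (V_mid = (i - 1/2) * vpc)
  key <- round(V_all / vpc - 0.5)
  F_mean <- tapply(F_all, key, mean)
  V_knots <- (as.numeric(names(F_mean)) + 0.5) * vpc
  ord <- order(V_knots)
  V_knots <- V_knots[ord]
  F_mean <- as.numeric(F_mean)[ord]
  # isotonic non-increasing projection (spring untwists)
  if (length(F_mean) >= 2)
    F_mean <- -isoreg(V_knots, -F_mean)$yf
  spring_curve(V_knots, pmax(F_mean, 0))
}

#' Check that a spring curve covers a flow series' volume range
#'
#' Emits a coverage warning if evaluating the curve on `flow`'s volume
#' midpoints would extrapolate; returns `TRUE`/`FALSE` invisibly.
#'
#' @param spring a [spring_curve()].
#' @param flow a `flow_series`.
#' @export
spring_covers <- function(spring, flow) {
  ok <- min(flow$V_mid) >= min(spring$V_knots) - 1e-15 &&
    max(flow$V_mid) <= max(spring$V_knots) + 1e-15
  if (!ok)
    pp_warn("spring_coverage", paste(
      "spring curve does not cover the injection's volume range;",
      "flat extrapolation will be used"))
  invisible(ok)
}

#' Export a spring curve as CSV (columns `V_uL`, `F_N`)
#'
#' @param spring a [spring_curve()].
#' @param path file path.
#' @export
write_spring_curve <- function(spring, path) {
  write.csv(data.frame(V_uL = m3_to_uL(spring$V_knots), F_N = spring$F_knots),
            path, row.names = FALSE)
  invisible(path)
}
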