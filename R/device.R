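#' Device geometry and fluid properties
#'
#' `device_geometry()` describes the pen: inner syringe radius `r_s`, inner
#' needle radius `r_n`, needle length `L_n` (6 mm for the 31G pen needle),
#' and the dimensionless coefficient `alpha_kinetic` on the kinetic/entry
#' pressure term (2 = kinetic-energy flux of a parabolic profile).
#' `fluid_props()` describes the drug, which for dilute insulin is taken as
#' water: dynamic viscosity `mu` (Pa s) and density `rho` (kg/m^3); the
#' kinematic viscosity `nu = mu/rho` is derived.
#'
#' @param r_s inner syringe radius, m (default 4.75 mm, a 3 mL cartridge).
#' @param r_n inner needle radius, m (default 66.5 um).
#' @param L_n needle length, m (default 6 mm).
#' @param alpha_kinetic kinetic-term coefficient (default 2).
#' @return a `device_geometry` / `fluid_props` list.
#' @export
device_geometry <- function(r_s = 4.75e-3, r_n = 66.5e-6, L_n = 6e-3,
                            alpha_kinetic = 2) {
  if (any(c(r_s, r_n, L_n) <= 0))
    pp_stop("invalid_input", "all device lengths must be positive")
  if (r_n >= r_s)
    pp_stop("invalid_input", "needle radius must be smaller than syringe radius")
  if (alpha_kinetic < 0)
    pp_stop("invalid_input", "alpha_kinetic must be >= 0")
  structure(list(r_s = r_s, r_n = r_n, L_n = L_n,
                 alpha_kinetic = alpha_kinetic),
            class = "device_geometry")
}

#' @rdname device_geometry
#' @param mu dynamic viscosity, Pa s (default 1.0e-3, water at ~20 C).
#' @param rho mass density, kg/m^3 (default 1000).
#' @export
fluid_props <- function(mu = 1.0e-3, rho = 1000) {
  if (mu <= 0 || rho <= 0)
    pp_stop("invalid_input", "mu and rho must be positive")
  structure(list(mu = mu, rho = rho, nu = mu / rho), class = "fluid_props")
}

#' Pressure drop along the needle
#'
#' The needle drop is a fully developed Poiseuille term plus a kinetic /
#' entry term quadratic in the flow:
#' \deqn{\Delta p = \frac{8 \mu L_n Q}{\pi r_n^4}
#'       + \alpha \frac{\rho Q^2}{2 \pi^2 r_n^4}.}
#' At pen flow rates (100-150 uL/s through a 31G needle) both terms are of
#' order 1e5 Pa, so neither may be dropped.
#'
#' @param Q flow rate, m^3/s (vectorised, must be >= 0).
#' @param geom a [device_geometry()].
#' @param fluid a [fluid_props()].
#' @return pressure drop in Pa.
#' @examples
#' needle_pressure_drop(uL_to_m3(100), device_geometry(), fluid_props())
#' @export
needle_pressure_drop <- function(Q, geom, fluid) {
  if (any(Q < 0)) pp_stop("invalid_input", "Q must be >= 0")
  r4 <- geom$r_n^4
  8 * fluid$mu * geom$L_n * Q / (pi * r4) +
    geom$alpha_kinetic * fluid$rho * Q^2 / (2 * pi^2 * r4)
}

#' Needle-outlet pressure from spring force and flow
#'
#' The pressure balance of the device: the spring force over the piston
#' area, minus the needle drop, is the pressure at the needle outlet (the
#' tissue pressure at the tip during an injection):
#' `p2 = F / (pi r_s^2) - needle_pressure_drop(Q)`.
#' Pressures are absolute; `F` is whatever the calibration defined it
#' against (see [calibrate_spring()]), so the convention cancels in the
#' counter pressure.
#'
#' @param F_spring spring force, N (vectorised).
#' @param Q flow rate, m^3/s.
#' @inheritParams needle_pressure_drop
#' @return outlet pressure p2 in Pa.
#' @export
outlet_pressure <- function(F_spring, Q, geom, fluid) {
  if (any(F_spring < 0)) pp_stop("invalid_input", "F_spring must be >= 0")
  F_spring / (pi * geom$r_s^2) - needle_pressure_drop(Q, geom, fluid)
}

#' Spring force implied by an outlet pressure and flow
#'
#' Exact algebraic inverse of [outlet_pressure()]:
#' `F = pi r_s^2 (p2 + needle_pressure_drop(Q))`.  Used for spring
#' calibration from air injections, where `p2` is atmospheric.  A negative
#' result is non-physical and flagged with a warning but still returned.
#'
#' @param p2 outlet pressure, Pa.
#' @inheritParams outlet_pressure
#' @return spring force in N.
#' @export
spring_force_from_outlet <- function(p2, Q, geom, fluid) {
  F_spring <- pi * geom$r_s^2 * (p2 + needle_pressure_drop(Q, geom, fluid))
  if (any(F_spring < 0))
    pp_warn("nonphysical_calibration",
            "calibrated spring force is negative for some intervals")
  F_spring
}

#' Needle radius from a calibration flow measurement
#'
#' After each injection the needle's inner radius is back-calculated from
#' the measured flow at a known driving pressure, inverting the needle-drop
#' expression (both terms share the `r_n^-4` factor):
#' `r_n = [(8 mu L_n Q / pi + alpha rho Q^2 / (2 pi^2)) / delta_p]^(1/4)`.
#'
#' @param delta_p driving pressure drop across the needle, Pa (> 0).
#' @param Q measured flow, m^3/s (> 0).
#' @param L_n needle length, m.
#' @param fluid a [fluid_props()].
#' @param alpha_kinetic kinetic-term coefficient (default 2).
#' @return needle inner radius in m.
#' @export
needle_radius_from_flow <- function(delta_p, Q, L_n, fluid,
                                    alpha_kinetic = 2) {
  if (any(delta_p <= 0) || any(Q <= 0))
    pp_stop("invalid_input", "delta_p and Q must be positive")
  ((8 * fluid$mu * L_n * Q / pi +
      alpha_kinetic * fluid$rho * Q^2 / (2 * pi^2)) / delta_p)^(1 / 4)
}

#' Diagnostics on the device pressure balance
#'
#' `needle_to_syringe_drop_ratio()` is the ratio of the needle's Poiseuille
#' drop to the (neglected) fully developed Poiseuille drop along the syringe
#' bore of length `L_s`; the model requires it to be much greater than 1.
#' `kinetic_to_viscous_ratio()` is the ratio of the kinetic to the viscous
#' needle term, `alpha rho Q / (16 pi mu L_n)`; at 100-150 uL/s it is of
#' order 1, which is why the kinetic term is kept.
#'
#' @inheritParams needle_pressure_drop
#' @param L_s syringe bore length, m (default 50 mm).
#' @return a dimensionless ratio.
#' @export
needle_to_syringe_drop_ratio <- function(Q, geom, fluid, L_s = 50e-3) {
  (geom$L_n / geom$r_n^4) / (L_s / geom$r_s^4)
}

#' @rdname needle_to_syringe_drop_ratio
#' @export
kinetic_to_viscous_ratio <- function(Q, geom, fluid) {
  geom$alpha_kinetic * fluid$rho * Q / (16 * pi * fluid$mu * geom$L_n)
}

# Internal: second-order Jensen bias of the needle drop evaluated at a
# flow estimated from jittered click intervals.  White timing noise of SD
# timing_sd inflates E[1/dt] by rho = 2 timing_sd^2/dt^2 and meets the
# convex drop law, so E[dp(Q_obs)] - dp(Q_true) ~ dp'(Q) Q rho
# + dp''(Q) Q^2 rho / 2.  Returned in Pa; subtracted during calibration
# and added back when reading tissue pressure, so it cancels identically
# for identical flows.
pp_needle_drop_bias <- function(Q, dt, timing_sd, geom, fluid) {
  if (timing_sd <= 0) return(rep(0, length(Q)))
  rho <- 2 * timing_sd^2 / dt^2
  r4 <- geom$r_n^4
  dP1 <- 8 * fluid$mu * geom$L_n / (pi * r4) +
    geom$alpha_kinetic * fluid$rho * Q / (pi^2 * r4)
  dP2 <- geom$alpha_kinetic * fluid$rho / (pi^2 * r4)
  dP1 * Q * rho + 0.5 * dP2 * Q^2 * rho
}
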