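#' Tissue parameters for the poro-elastic pressure model
#'
#' The tissue around the needle tip is modelled as a homogeneous, isotropic
#' porous elastic medium.  Injected fluid moves by Darcy flow
#' (`u = -(k/mu) dp/dr`), and displacing the tissue raises the local
#' porosity `phi` above its background value `phi0` against a restoring
#' pressure: `p = p0 + K (phi - phi0)` — a linear law valid for moderate
#' over-pressures only.
#'
#' @param k permeability, m^2 (adipose tissue: order 1e-11 to 1e-10).
#' @param K effective bulk modulus, Pa (order 1e5).
#' @param phi0 background porosity, dimensionless in (0, 1); default 0.01
#'   (the undisturbed pore space available to the drug is very small).
#' @param p0 undisturbed tissue pressure, Pa, absolute; default atmospheric
#'   (the true subcutis pressure may sit slightly below it).
#' @return a `tissue_params` list.
#' @export
tissue_params <- function(k, K, phi0 = 0.01, p0 = 101325) {
  if (k <= 0 || K <= 0) pp_stop("invalid_input", "k and K must be positive")
  if (phi0 <= 0 || phi0 >= 1)
    pp_stop("invalid_input", "phi0 must be in (0, 1)")
  if (p0 <= 0) pp_stop("invalid_input", "p0 must be positive (absolute)")
  structure(list(k = k, K = K, phi0 = phi0, p0 = p0),
            class = "tissue_params")
}

#' Logarithmic radial grid for the pressure solver
#'
#' Finite-volume cells between the needle surface (`r_inner`, taken equal
#' to the needle radius, where the flux boundary condition is applied) and
#' a far-field radius `r_outer` held at the undisturbed pressure.  Faces are
#' geometrically spaced; cell centres sit at the geometric mean of their
#' faces, concentrating resolution near the needle where the pressure
#' varies as 1/r.
#'
#' @param r_inner inner radius, m (> 0); typically the needle radius.
#' @param r_outer far-field radius, m; must be at least `100 * r_inner`.
#' @param n number of cells (default 200).
#' @return a `radial_grid` with faces, centres, areas and volumes.
#' @export
radial_grid <- function(r_inner, r_outer = 50e-3, n = 200L) {
  if (r_inner <= 0) pp_stop("invalid_input", "r_inner must be positive")
  if (r_outer < 100 * r_inner)
    pp_stop("invalid_input", "r_outer must be at least 100 * r_inner")
  n <- as.integer(n)
  if (n < 10L || n > 2048L)
    pp_stop("invalid_input", "n must be between 10 and 2048")
  faces <- r_inner * (r_outer / r_inner)^(seq(0, n) / n)
  centres <- sqrt(faces[-1] * faces[-(n + 1)])
  structure(list(
    r = centres,
    faces = faces,
    r_inner = r_inner,
    r_outer = r_outer,
    n = n,
    A = 4 * pi * faces^2,
    V = 4 * pi / 3 * (faces[-1]^3 - faces[-(n + 1)]^3)
  ), class = "radial_grid")
}

# Internal: piecewise-linear forcing table for Q(t) over [0, t_end].
# Flow series are interpolated linearly between interval midpoints with
# constant extension at both edges; functions are sampled densely;
# scalars become constants.
pp_forcing_table <- function(Q, t_end) {
  if (inherits(Q, "flow_series")) {
    tt <- Q$t_mid
    qq <- Q$Q
    if (tt[1] > 0) { tt <- c(0, tt); qq <- c(qq[1], qq) }
    if (tt[length(tt)] < t_end) {
      tt <- c(tt, t_end)
      qq <- c(qq, qq[length(qq)])
    }
    cbind(tt, qq)
  } else if (is.function(Q)) {
    tt <- seq(0, t_end, length.out = max(256L, 64L * ceiling(t_end)))
    cbind(tt, vapply(tt, Q, numeric(1)))
  } else if (is.numeric(Q) && length(Q) == 1) {
    cbind(c(0, t_end), c(Q, Q))
  } else {
    pp_stop("invalid_input", "Q must be a flow_series, function, or scalar")
  }
}

# Internal: exact integral of a piecewise-linear forcing table on [0, t].
pp_forcing_integral <- function(tab, t_end) {
  tt <- c(tab[, 1], t_end)
  qq <- c(tab[, 2], approx(tab[, 1], tab[, 2], t_end, rule = 2)$y)
  o <- order(tt)
  tt <- tt[o]; qq <- qq[o]
  keep <- tt >= 0 & tt <= t_end
  tt <- tt[keep]; qq <- qq[keep]
  sum(diff(tt) * (head(qq, -1) + tail(qq, -1)) / 2)
}

PP_MAXN <- 2048L

#' Solve the spherically symmetric poro-elastic pressure equation
#'
#' Integrates
#' \deqn{\frac{\partial p}{\partial t} = \frac{K k}{\mu}\,
#'   \frac{1}{r^2}\frac{\partial}{\partial r}
#'   \left(r^2 \phi \frac{\partial p}{\partial r}\right), \qquad
#'   \phi = \phi_0 + \frac{p - p_0}{K},}
#' with the injected flow prescribed as a flux boundary condition at the
#' needle surface (mass cannot accumulate in the infinitesimal tip volume):
#' `4 pi r_inner^2 phi u_r = Q(t)` with `u_r = -(k/mu) dp/dr`, and the far
#' field held at `p0`.  Discretisation is conservative finite volumes on a
#' logarithmic grid; time integration is `deSolve::lsoda` with a banded
#' Jacobian and a compiled right-hand side.
#'
#' The porosity entering the mobility is clamped to `[eps_phi, 1]`; the
#' linear pressure-porosity law can push `phi` towards (or nominally past)
#' unity right at the needle at high pressure, where the law is known to
#' break down, and clamp events are counted in the diagnostics.  With
#' `linearised = TRUE` the mobility uses the constant background `phi0`
#' (and so does the boundary flux), giving the linear spherical diffusion
#' equation with diffusivity `D = K k phi0 / mu` — the regime in which the
#' closed-form [steady_state_pressure()] is exact.
#'
#' @param params a [tissue_params()].
#' @param Q injected flow: a `flow_series` (linear interpolation between
#'   interval midpoints, constant at the edges), a function of time, or a
#'   constant scalar (m^3/s).
#' @param fluid a [fluid_props()].
#' @param grid a [radial_grid()].
#' @param t_eval output times, s, increasing, starting at 0 (where
#'   `p = p0` everywhere).
#' @param linearised use `phi0` in the mobility and boundary flux.
#' @param rtol,atol relative / absolute (Pa) integration tolerances.
#' @param eps_phi lower porosity clamp.
#' @return a `pressure_solution`: list with `t`, `r`, matrices `p` and
#'   `phi` (time by radius), the needle-tip trace `p_tip`, `Q_used`, the
#'   generating `params`, `grid`, `fluid`, and `diagnostics` (mass-balance
#'   residual as a fraction of injected volume, clamp event count).
#' @export
solve_pressure <- function(params, Q, fluid, grid, t_eval,
                           linearised = FALSE, rtol = 1e-6, atol = 1e-2,
                           eps_phi = 1e-6) {
  stopifnot(inherits(params, "tissue_params"), inherits(grid, "radial_grid"),
            inherits(fluid, "fluid_props"))
  t_eval <- as.numeric(t_eval)
  if (t_eval[1] != 0 || any(diff(t_eval) <= 0))
    pp_stop("invalid_input", "t_eval must increase from 0")
  n <- grid$n
  t_end <- t_eval[length(t_eval)]
  ftab <- pp_forcing_table(Q, t_end)
  if (any(ftab[, 2] < 0))
    pp_stop("invalid_input", "Q must be non-negative")

  centres <- grid$r
  parms <- numeric(8 + 3 * PP_MAXN + 2)
  parms[1] <- n
  parms[2] <- params$k / fluid$mu
  parms[3] <- params$K
  parms[4] <- params$phi0
  parms[5] <- params$p0
  parms[6] <- as.numeric(linearised)
  parms[7] <- eps_phi
  parms[8] <- 1 / (grid$r_outer - centres[n])
  parms[8 + seq_len(n + 1)] <- grid$A
  parms[8 + n + 1 + seq_len(n)] <- grid$V
  parms[8 + 2 * n + 1 + seq_len(n - 1)] <- 1 / diff(centres)

  y0 <- rep(params$p0, n)
  sol <- deSolve::ode(
    y = y0, times = t_eval, func = "pp_derivs", parms = parms,
    dllname = "penpress", initfunc = "pp_initmod", initforc = "pp_initforc",
    forcings = ftab, fcontrol = list(method = "linear", rule = 2),
    method = "lsoda", jactype = "bandint", bandup = 1L, banddown = 1L,
    rtol = rtol, atol = atol, maxsteps = 200000L
  )
  if (attr(sol, "istate")[1] < 0)
    pp_stop("stiffness_failure", "pressure solver failed to integrate")

  p <- unname(sol[, -1, drop = FALSE])
  phi_raw <- params$phi0 + (p - params$p0) / params$K
  if (any(phi_raw <= 0))
    pp_stop("stiffness_failure",
            "porosity collapsed to zero; parameters outside the model's regime")
  clamp_events <- sum(phi_raw > 1 | phi_raw < eps_phi)
  phi <- pmax(pmin(phi_raw, 1), eps_phi)  # matrix first: keeps dims

  Q_used <- approx(ftab[, 1], ftab[, 2], t_eval, rule = 2)$y

  # tip pressure: quasi-steady Darcy profile between the needle surface and
  # the first cell centre (the near field equilibrates on the r_inner^2/D
  # scale, orders of magnitude faster than the injection)
  phi_tip <- if (linearised) rep(params$phi0, length(t_eval)) else phi[, 1]
  geom_fac <- 1 / grid$r_inner - 1 / centres[1]
  p_tip <- p[, 1] +
    Q_used * fluid$mu / (4 * pi * params$k * phi_tip) * geom_fac
  if (!linearised) {
    # one fixed-point refinement with the porosity at the tip itself
    phi_tip <- pmin(1, pmax(eps_phi,
                            params$phi0 + (p_tip - params$p0) / params$K))
    p_tip <- p[, 1] +
      Q_used * fluid$mu / (4 * pi * params$k * phi_tip) * geom_fac
  }

  # mass balance: stored (via the exact law, which the scheme conserves)
  # plus cumulative outflux through the far boundary vs injected volume
  stored <- sum((p[length(t_eval), ] - params$p0) / params$K * grid$V)
  mob_out <- if (linearised) rep(params$phi0, length(t_eval)) else phi[, n]
  flux_out <- (params$k / fluid$mu) * mob_out *
    (p[, n] - params$p0) * parms[8] * grid$A[n + 1]
  outflux <- sum(diff(t_eval) * (head(flux_out, -1) + tail(flux_out, -1)) / 2)
  injected <- pp_forcing_integral(ftab, t_end)
  resid <- if (injected > 0) (stored + outflux - injected) / injected else 0

  structure(list(
    t = t_eval, r = centres, p = p, phi = phi, p_tip = p_tip,
    Q_used = Q_used, params = params, grid = grid, fluid = fluid,
    linearised = linearised,
    diagnostics = list(mass_balance_residual = resid,
                       clamp_events = clamp_events,
                       injected_volume = injected,
                       stored_volume = stored,
                       outflux_volume = outflux)
  ), class = "pressure_solution")
}

#' @export
print.pressure_solution <- function(x, ...) {
  cat(sprintf(paste0(
    "<pressure_solution> %d times x %d cells, r %.2g..%.2g mm\n",
    "  tip over-pressure at t_end: %.1f mbar; mass residual %.2e;",
    " clamp events %d\n"),
    length(x$t), length(x$r), 1e3 * x$grid$r_inner, 1e3 * x$grid$r_outer,
    Pa_to_mbar(x$p_tip[length(x$t)] - x$params$p0),
    x$diagnostics$mass_balance_residual, x$diagnostics$clamp_events))
  invisible(x)
}

#' Closed-form steady over-pressure of the linearised model
#'
#' In the small-disturbance limit (`phi` close to `phi0`) the steady state
#' of the pressure equation with a point-like source of strength `Q` is
#' \deqn{p(r) = p_0 + \frac{Q \mu}{4 \pi k \phi_0 r}.}
#' Used as an independent oracle for the finite-volume solver.
#'
#' @param params a [tissue_params()].
#' @param Q flow rate, m^3/s (>= 0).
#' @param fluid a [fluid_props()].
#' @param r radii, m.
#' @return pressure in Pa.
#' @export
steady_state_pressure <- function(params, Q, fluid, r) {
  if (Q < 0) pp_stop("invalid_input", "Q must be >= 0")
  params$p0 + Q * fluid$mu / (4 * pi * params$k * params$phi0 * r)
}

#' Darcy velocity field of a pressure solution
#'
#' `u_r = -(k/mu) dp/dr`, by central differences on the cell centres (one-
#' sided at the ends).  At the needle the product `4 pi r^2 phi u_r`
#' reproduces the injected flow by construction of the boundary condition.
#'
#' @param solution a `pressure_solution`.
#' @param fluid a [fluid_props()]; defaults to the one stored in `solution`.
#' @return matrix (time by radius) of radial velocities, m/s.
#' @export
darcy_velocity <- function(solution, fluid = solution$fluid) {
  p <- solution$p
  r <- solution$r
  n <- length(r)
  grad <- p
  grad[, 1] <- (p[, 2] - p[, 1]) / (r[2] - r[1])
  grad[, n] <- (p[, n] - p[, n - 1]) / (r[n] - r[n - 1])
  if (n > 2) {
    idx <- 2:(n - 1)
    grad[, idx] <- sweep(p[, idx + 1, drop = FALSE] -
                           p[, idx - 1, drop = FALSE],
                         2, r[idx + 1] - r[idx - 1], "/")
  }
  -(solution$params$k / fluid$mu) * grad
}

#' Depot radius: extent of the over-pressurised region
#'
#' The largest radius at which the over-pressure `p - p0` at the final
#' output time still exceeds `fraction` of its value at the needle surface.
#' Interpolation is linear in log-log coordinates, exact for the 1/r
#' near-field profile.  Returns `r_inner` when there is no over-pressure.
#'
#' @param solution a `pressure_solution`.
#' @param fraction threshold as a fraction of the tip over-pressure,
#'   in (0, 1); default 0.1.
#' @return radius in m.
#' @export
depot_radius <- function(solution, fraction = 0.1) {
  if (fraction <= 0 || fraction >= 1)
    pp_stop("invalid_input", "fraction must be in (0, 1)")
  i_end <- length(solution$t)
  p0 <- solution$params$p0
  over <- solution$p[i_end, ] - p0
  tip_over <- solution$p_tip[i_end] - p0
  if (tip_over <= 0) return(solution$grid$r_inner)
  thr <- fraction * tip_over
  r <- c(solution$grid$r_inner, solution$r)
  over <- c(tip_over, over)
  above <- over >= thr
  if (!above[1]) return(solution$grid$r_inner)
  if (all(above)) return(solution$grid$r_outer)
  j <- which(!above)[1] - 1L  # last index still above threshold
  if (over[j + 1] <= 0) return(r[j])
  # log-log linear crossing between r[j] and r[j+1]
  lr <- log(r[j:(j + 1)]); lo <- log(over[j:(j + 1)])
  exp(lr[1] + (log(thr) - lo[1]) * diff(lr) / diff(lo))
}

#' Export a pressure solution
#'
#' `write_pressure_solution()` writes the full field in long format
#' (`t_s`, `r_mm`, `p_Pa`, `phi`); `write_tip_trace()` writes the compact
#' needle-tip trace (`t_s`, `p_tip_Pa`).
#'
#' @param solution a `pressure_solution`.
#' @param path file path.
#' @export
write_pressure_solution <- function(solution, path) {
  df <- data.frame(
    t_s = rep(solution$t, times = length(solution$r)),
    r_mm = rep(1e3 * solution$r, each = length(solution$t)),
    p_Pa = as.vector(solution$p),
    phi = as.vector(solution$phi)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pressure_solution
#' @export
write_tip_trace <- function(solution, path) {
  write.csv(data.frame(t_s = solution$t, p_tip_Pa = solution$p_tip),
            path, row.names = FALSE)
  invisible(path)
}
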