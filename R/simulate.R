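# Coupled device-tissue forward simulator.  Used to validate every pipeline
# stage: it produces click trains whose ground truth (spring curve, tissue
# parameters, tip pressure) is known exactly.

# Internal: advance the PDE state by dt at constant Q (operator splitting).
pp_pde_step <- function(p_state, Q, dt, parms, rtol, atol) {
  sol <- deSolve::ode(
    y = p_state, times = c(0, dt), func = "pp_derivs", parms = parms,
    dllname = "penpress", initfunc = "pp_initmod", initforc = "pp_initforc",
    forcings = cbind(c(0, dt), c(Q, Q)),
    fcontrol = list(method = "linear", rule = 2),
    method = "lsoda", jactype = "bandint", bandup = 1L, banddown = 1L,
    rtol = rtol, atol = atol, maxsteps = 20000L
  )
  if (attr(sol, "istate")[1] < 0)
    pp_stop("stiffness_failure", "forward simulation: PDE step failed")
  unname(sol[2, -1])
}

# Internal: pack the C parameter vector for a grid/params combination.
pp_pack_parms <- function(params, fluid, grid, linearised = FALSE,
                          eps_phi = 1e-6) {
  n <- grid$n
  parms <- numeric(8 + 3 * PP_MAXN + 2)
  parms[1] <- n
  parms[2] <- params$k / fluid$mu
  parms[3] <- params$K
  parms[4] <- params$phi0
  parms[5] <- params$p0
  parms[6] <- as.numeric(linearised)
  parms[7] <- eps_phi
  parms[8] <- 1 / (grid$r_outer - grid$r[n])
  parms[8 + seq_len(n + 1)] <- grid$A
  parms[8 + n + 1 + seq_len(n)] <- grid$V
  parms[8 + 2 * n + 1 + seq_len(n - 1)] <- 1 / diff(grid$r)
  parms
}

#' Simulate one spring-driven injection (air or tissue)
#'
#' Advances the delivered volume by operator splitting at `dt` steps.  At
#' each step the scalar pressure balance
#' `F(V) = pi r_s^2 * (p_tip(Q) + needle_pressure_drop(Q))`
#' is solved for the flow `Q` by a bracketed root finder; in air the tip
#' pressure is the reference pressure, in tissue it comes from the
#' poro-elastic pressure state, which is then advanced by `dt` with that
#' flow held constant.  A click is emitted every `volume_per_click`
#' (crossing times interpolated within the step, exact for constant-Q
#' steps); optional Gaussian jitter models microphone timing error.  If the
#' spring cannot overcome the tissue pressure the injection stalls and the
#' partial dose is returned, flagged.
#'
#' @param spring a [spring_curve()] (absolute convention: includes the
#'   `pi r_s^2 p_ref` atmospheric contribution, as [calibrate_spring()]
#'   with the default `p_ref` would return).
#' @param tissue a [tissue_params()], or `"air"` for a reference injection.
#' @param geom a [device_geometry()].
#' @param fluid a [fluid_props()].
#' @param dose delivered volume, m^3; a positive multiple of
#'   `volume_per_click`.
#' @param jitter_sd click-time jitter SD, s (default 0.002).
#' @param seed optional RNG seed for the jitter.
#' @param volume_per_click m^3 per click (default 10 uL).
#' @param p_ref reference pressure, Pa.
#' @param dt coupling step, s (default 0.001).
#' @param grid_n,r_outer PDE grid (tissue case only).
#' @param append_tail_slow append two artificially slow trailing clicks to
#'   mimic the device's end-of-injection force drop (exercises the
#'   truncation rule; the mechanism itself is not modelled).
#' @return a `synthetic_injection`: `clicks` (jittered, the observable),
#'   `clicks_true`, `flow` (from the observable clicks, untruncated),
#'   `tip_pressure` (a `pressure_series` of true tip pressures at the true
#'   interval midpoints), `truth` (`tissue_params` or `"air"`),
#'   `spring_truth`, `stalled`, `seed`.
#' @export
simulate_injection <- function(spring, tissue, geom, fluid, dose,
                               jitter_sd = 0.002, seed = NULL,
                               volume_per_click = uL_to_m3(10),
                               p_ref = 101325, dt = 1e-3,
                               grid_n = 160L, r_outer = 50e-3,
                               append_tail_slow = FALSE) {
  stopifnot(inherits(spring, "spring_curve"))
  in_air <- identical(tissue, "air")
  if (!in_air) stopifnot(inherits(tissue, "tissue_params"))
  n_clicks <- round(dose / volume_per_click)
  if (n_clicks < 2 || abs(n_clicks * volume_per_click - dose) > 1e-12 * dose)
    pp_stop("invalid_input",
            "dose must be a positive multiple of volume_per_click (>= 2 clicks)")
  if (!is.null(seed)) set.seed(seed)
  medium <- if (in_air) "air" else "tissue"
  area <- pi * geom$r_s^2

  grid <- NULL; parms <- NULL; p_state <- NULL
  if (!in_air) {
    grid <- radial_grid(geom$r_n, r_outer, grid_n)
    parms <- pp_pack_parms(tissue, fluid, grid)
    p_state <- rep(tissue$p0, grid$n)
  }

  tip_pressure_at <- function(Q) {
    if (in_air) return(p_ref)
    geom_fac <- 1 / grid$r_inner - 1 / grid$r[1]
    phi_tip <- max(1e-6, min(1, tissue$phi0 + (p_state[1] - tissue$p0) / tissue$K))
    for (it in 1:3) {
      p_tip <- p_state[1] +
        Q * fluid$mu / (4 * pi * tissue$k * phi_tip) * geom_fac
      phi_tip <- max(1e-6, min(1, tissue$phi0 + (p_tip - tissue$p0) / tissue$K))
    }
    p_tip
  }

  solve_Q <- function(F_now) {
    drive <- F_now / area
    g <- function(Q) drive - tip_pressure_at(Q) - needle_pressure_drop(Q, geom, fluid)
    if (g(0) <= 0) return(0)  # stalled: spring cannot overcome tip pressure
    # bracket: flow at which the needle drop alone absorbs the full drive
    a <- 8 * fluid$mu * geom$L_n / (pi * geom$r_n^4)
    b <- geom$alpha_kinetic * fluid$rho / (2 * pi^2 * geom$r_n^4)
    Q_hi <- if (b > 0) (-a + sqrt(a^2 + 4 * b * drive)) / (2 * b) else drive / a
    Q_hi <- 1.01 * Q_hi + 1e-12
    if (g(Q_hi) > 0) return(Q_hi)  # degenerate; should not happen
    uniroot(g, c(0, Q_hi), tol = 1e-18)$root
  }

  V <- 0; t_now <- 0
  next_click <- volume_per_click
  click_times <- numeric(0)
  t_trace <- 0
  ptip_trace <- tip_pressure_at(0)
  Q_trace <- numeric(0)
  stalled <- FALSE
  max_steps <- 200000L

  for (step in seq_len(max_steps)) {
    F_now <- spring_force(spring, min(V, max(spring$V_knots)),
                          warn_extrapolate = FALSE)
    Q <- solve_Q(F_now)
    if (Q <= 0) { stalled <- TRUE; break }
    V_new <- V + Q * dt
    while (next_click <= V_new + 1e-18 &&
           length(click_times) < n_clicks) {
      click_times <- c(click_times, t_now + (next_click - V) / Q)
      next_click <- next_click + volume_per_click
    }
    if (!in_air) p_state <- pp_pde_step(p_state, Q, dt, parms,
                                        rtol = 1e-6, atol = 1e-2)
    V <- V_new
    t_now <- t_now + dt
    t_trace <- c(t_trace, t_now)
    ptip_trace <- c(ptip_trace, tip_pressure_at(Q))
    Q_trace <- c(Q_trace, Q)
    if (length(click_times) >= n_clicks) break
  }
  if (length(click_times) < n_clicks && !stalled)
    pp_stop("stiffness_failure", "simulation exceeded the step budget")

  # click i marks the completion of the i-th volume increment
  clicks_true <- click_train(click_times, volume_per_click,
                             subject_id = "synthetic", medium = medium)
  clicks <- if (jitter_sd > 0)
    jitter_click_train(clicks_true, jitter_sd) else clicks_true
  if (length(click_times) >= 2) {
    flow <- flow_from_clicks(clicks, truncate_tail = 0L)
    flow_true <- flow_from_clicks(clicks_true, truncate_tail = 0L)
    tip_mid <- approx(t_trace, ptip_trace, flow_true$t_mid, rule = 2)$y
    tip_series <- structure(data.frame(
      t_mid = flow_true$t_mid, V_mid = flow_true$V_mid,
      p2 = tip_mid, counter_pressure = tip_mid - p_ref
    ), class = c("pressure_series", "data.frame"),
    subject_id = "synthetic", p_ref = p_ref)
  } else {
    # stalled before the second click: no flow estimate is possible
    flow <- NULL
    tip_series <- NULL
  }

  if (append_tail_slow && length(clicks$times) >= 2) {
    dt_last <- diff(tail(clicks$times, 2))
    clicks <- click_train(c(clicks$times,
                            tail(clicks$times, 1) + 2 * dt_last,
                            tail(clicks$times, 1) + 5 * dt_last),
                          volume_per_click, clicks$subject_id, medium)
  }

  structure(list(
    truth = if (in_air) "air" else tissue,
    spring_truth = spring,
    clicks = clicks, clicks_true = clicks_true,
    flow = flow, tip_pressure = tip_series,
    Q_trace = data.frame(t = t_trace[-1], Q = Q_trace),
    delivered = V, dose = dose, stalled = stalled,
    jitter_sd = jitter_sd, seed = seed, p_ref = p_ref
  ), class = "synthetic_injection")
}

#' @export
print.synthetic_injection <- function(x, ...) {
  med <- if (identical(x$truth, "air")) "air" else "tissue"
  cat(sprintf(
    "<synthetic_injection> %s, %d clicks, dose %.0f uL%s\n",
    med, length(x$clicks$times), m3_to_uL(x$dose),
    if (x$stalled) " [STALLED]" else ""))
  invisible(x)
}

#' Simulate a synthetic cohort of paired air/tissue injections
#'
#' For each subject: tissue permeability and bulk modulus drawn
#' log-uniformly from the given ranges, a linear spring with initial air
#' flow around 140-155 uL/s decelerating towards ~80 uL/s at the largest
#' dose, a dose uniform over `dose_range` rounded to whole clicks, two air
#' reference injections (before/after) and one tissue injection.  Fully
#' reproducible from `seed`.
#'
#' @param n_subjects number of subjects (default 11).
#' @param k_range permeability range, m^2 (log-uniform).
#' @param K_range bulk-modulus range, Pa (log-uniform).
#' @param dose_range dose range, m^3 (default 180-480 uL).
#' @param jitter_sd click jitter SD, s.
#' @param seed RNG seed.
#' @param geom,fluid device and fluid (defaults as shipped).
#' @param phi0,p0,p_ref model constants.
#' @param volume_per_click m^3 per click.
#' @param grid_n PDE resolution for the tissue simulations.
#' @return list of subjects, each a list with `subject_id`, `truth`,
#'   `spring_truth`, `air` (list of two `synthetic_injection`s) and
#'   `tissue` (one `synthetic_injection`).
#' @export
make_cohort <- function(n_subjects = 11L,
                        k_range = c(1e-11, 1e-10),
                        K_range = c(3e4, 3e5),
                        dose_range = uL_to_m3(c(180, 480)),
                        jitter_sd = 0.002, seed = 1L,
                        geom = device_geometry(), fluid = fluid_props(),
                        phi0 = 0.01, p0 = 101325, p_ref = 101325,
                        volume_per_click = uL_to_m3(10),
                        grid_n = 160L) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  draws <- data.frame(
    k = 10^runif(n_subjects, log10(k_range[1]), log10(k_range[2])),
    K = 10^runif(n_subjects, log10(K_range[1]), log10(K_range[2])),
    F0 = runif(n_subjects, 22.5, 24.5),
    slope = runif(n_subjects, 1.8e7, 2.3e7),
    dose = round(runif(n_subjects, dose_range[1], dose_range[2]) /
                   volume_per_click) * volume_per_click
  )
  lapply(seq_len(n_subjects), function(i) {
    id <- sprintf("SYN%02d", i)
    d <- draws[i, ]
    V_max <- d$dose + 2 * volume_per_click
    spring <- spring_curve(c(0, V_max),
                           c(d$F0, max(0, d$F0 - d$slope * V_max)))
    truth <- tissue_params(d$k, d$K, phi0, p0)
    sim1 <- function(tis, sd_seed, med_id) {
      s <- simulate_injection(spring, tis, geom, fluid, d$dose,
                              jitter_sd = jitter_sd, seed = sd_seed,
                              volume_per_click = volume_per_click,
                              p_ref = p_ref, grid_n = grid_n)
      s$clicks$subject_id <- id
      s$clicks_true$subject_id <- id
      attr(s$flow, "subject_id") <- id
      attr(s$tip_pressure, "subject_id") <- id
      s
    }
    base <- seed * 1000L + i * 10L
    list(subject_id = id, truth = truth, spring_truth = spring,
         air = list(sim1("air", base + 1L, id), sim1("air", base + 2L, id)),
         tissue = sim1(truth, base + 3L, id))
  })
}
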