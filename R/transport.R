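#' Aerosol source configuration
#'
#' Particle size distribution of the inhaled aerosol. The default is the
#' log-normal distribution of aerosolized iodine particles with count-median
#' diameter 0.42 um and geometric standard deviation 3.5; a `"uniform"`
#' source gives a single (monodisperse) size.
#'
#' @param distribution `"lognormal"` or `"uniform"`.
#' @param cmd_um count-median diameter, um (log-normal).
#' @param gsd geometric standard deviation, > 1 (log-normal).
#' @param size_um fixed diameter, um (uniform source).
#' @param range_um optional truncation range `c(lo, hi)` in um.
#' @return object of class `particle_source`.
#' @export
particle_source <- function(distribution = c("lognormal", "uniform"),
                            cmd_um = 0.42, gsd = 3.5, size_um = NULL,
                            range_um = NULL) {
  distribution <- match.arg(distribution)
  if (distribution == "lognormal") {
    check_positive(cmd_um, "cmd_um")
    if (gsd <= 1) stopf("'gsd' must be > 1")
  } else {
    check_positive(size_um, "size_um")
  }
  structure(list(distribution = distribution, cmd_um = cmd_um, gsd = gsd,
                 size_um = size_um, range_um = range_um),
            class = "particle_source")
}

#' Sample particle diameters from a source
#'
#' Draws diameters (um) from the source distribution; deterministic for a
#' fixed seed. Log-normal sampling uses meanlog = log(cmd) and
#' sdlog = log(gsd), so the sample geometric mean recovers the count-median
#' diameter. Truncation, if configured, is by rejection.
#'
#' @param n number of diameters.
#' @param source a [particle_source()].
#' @param seed optional integer seed (set before drawing when given).
#' @return numeric vector of diameters in um.
#' @export
sample_particle_sizes <- function(n, source = particle_source(), seed = NULL) {
  if (n < 1) stopf("'n' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (source$distribution == "uniform")
    return(rep(source$size_um, n))
  draw <- function(m) stats::rlnorm(m, meanlog = log(source$cmd_um),
                                    sdlog = log(source$gsd))
  d <- draw(n)
  if (!is.null(source$range_um)) {
    lo <- source$range_um[1]; hi <- source$range_um[2]
    bad <- which(d < lo | d > hi)
    while (length(bad) > 0) {
      d[bad] <- draw(length(bad))
      bad <- bad[d[bad] < lo | d[bad] > hi]
    }
  }
  d
}

#' Schiller-Naumann drag coefficient
#'
#' C_d = (24/Re)(1 + 0.15 Re^0.687) for 0 < Re <= 1000 and C_d = 0.44 above
#' (Newton plateau). At Re = 0 the coefficient diverges but the product
#' C_d Re -> 24 (Stokes law); the tracker therefore never multiplies by C_d
#' directly but uses the bounded factor [drag_factor()].
#'
#' @param Re_p particle Reynolds number, >= 0 (vectorized).
#' @return drag coefficient (Inf at Re = 0).
#' @export
drag_coefficient <- function(Re_p) {
  if (any(Re_p < 0)) stopf("'Re_p' must be >= 0")
  ifelse(Re_p > 1000, 0.44,
         ifelse(Re_p == 0, Inf, 24 / Re_p * (1 + 0.15 * Re_p^0.687)))
}

#' Drag nonlinearity factor C_d Re / 24
#'
#' The factor multiplying the Stokes friction in the linearized-in-slip form
#' of the drag force; equals 1 in the Stokes limit and stays finite for all
#' Re >= 0.
#'
#' @param Re_p particle Reynolds number (vectorized).
#' @return dimensionless factor >= 1.
#' @export
drag_factor <- function(Re_p) {
  ifelse(Re_p > 1000, 0.44 * Re_p / 24, 1 + 0.15 * Re_p^0.687)
}

#' Cunningham slip correction factor
#'
#' 1 + Kn (1.257 + 0.4 exp(-1.1/Kn)) with Kn = 2 lambda / d and mean free
#' path lambda = 68 nm. Off by default in the tracker (the drag model is the
#' continuum Schiller-Naumann correlation); enable via the simulation
#' config.
#'
#' @param d_p particle diameter, m (vectorized).
#' @param mfp_m mean free path of air, m.
#' @return slip correction (>= 1).
#' @export
cunningham_correction <- function(d_p, mfp_m = 68e-9) {
  Kn <- 2 * mfp_m / d_p
  1 + Kn * (1.257 + 0.4 * exp(-1.1 / Kn))
}

#' Brownian force sample
#'
#' Random thermal force with per-axis amplitude sqrt(2 k_b T gamma_f / dt)
#' where gamma_f = 3 pi eta d is the Stokes friction coefficient (the
#' inverse of the particle mobility). This fluctuation-dissipation form
#' yields a mean-squared displacement 2 D t with D = k_b T / gamma_f
#' (Einstein relation). `printed_form = TRUE` instead places the mobility
#' itself under the square root, for comparison with the literature variant
#' that prints the mobility in the numerator.
#'
#' @param d_p particle diameter, m (scalar or length-n).
#' @param air an [air_properties()].
#' @param dt time step, s.
#' @param n number of force vectors to draw.
#' @param printed_form use the mobility-in-numerator variant.
#' @return n x 3 matrix of forces, N.
#' @export
brownian_kick <- function(d_p, air, dt, n = 1, printed_form = FALSE) {
  check_positive(dt, "dt")
  gamma_f <- 3 * pi * air$viscosity * d_p
  coeff <- if (printed_form) 1 / gamma_f else gamma_f
  amp <- sqrt(2 * air$k_b * air$temperature * coeff / dt)
  matrix(stats::rnorm(3 * n), n, 3) * amp
}

#' Brownian diffusion coefficient (Einstein relation)
#'
#' D = k_b T / (3 pi eta d).
#'
#' @param d_p particle diameter, m (vectorized).
#' @param air an [air_properties()].
#' @return diffusivity, m^2/s.
#' @export
particle_diffusivity <- function(d_p, air = air_properties()) {
  air$k_b * air$temperature / (3 * pi * air$viscosity * d_p)
}

#' Particle relaxation time
#'
#' tau_p = rho_p d_p^2 / (18 eta): the Stokes-drag velocity relaxation time.
#'
#' @param d_p diameter, m.
#' @param rho_p particle density, kg/m^3.
#' @param air an [air_properties()].
#' @return tau_p in seconds.
#' @export
particle_relaxation_time <- function(d_p, rho_p, air = air_properties()) {
  rho_p * d_p^2 / (18 * air$viscosity)
}

#' Simulation configuration for the Lagrangian tracker
#'
#' @param n_particles number of particles to inject (one particle per
#'   parcel).
#' @param rho_p particle density, kg/m^3 (default 4390, solid iodine).
#' @param dt_flow carrier-flow update step, s (default 0.02, within the
#'   0.015-0.025 s range used for the flow solution).
#' @param t_total total simulated time, s (default 4: one flow-only cycle
#'   then one cycle with particles).
#' @param injection_window `c(t0, t1)` over which particles are injected
#'   (default `c(2, 3)`, the inhalation of the second cycle); a zero-width
#'   window injects everything at `t0`.
#' @param forces character subset of
#'   `c("drag", "gravity", "brownian", "lift", "virtual_mass")`.
#' @param gravity gravitational acceleration vector, m/s^2; `NULL` (default)
#'   uses 9.81 along the tree's gravity axis.
#' @param alpha_p particle volume fraction in the gravity buoyancy factor
#'   (1 - alpha_p); default 0 (dilute limit).
#' @param cunningham apply the Cunningham slip correction to the drag
#'   (default FALSE).
#' @param brownian_printed_form use the mobility-in-numerator Brownian
#'   amplitude variant (default FALSE; see [brownian_kick()]).
#' @param substep_transit_frac segment transit fraction per particle
#'   sub-step (default 1/20); the sub-step is
#'   `min(dt_flow, frac * L_seg / u_char)` over occupied segments.
#' @param profile velocity profile kind, `"parabolic"` or `"plug"`.
#' @param snapshot_times times (s) at which the airborne size spectrum is
#'   recorded (for [size_histogram()]).
#' @param seed integer RNG seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_particles = 1e5, rho_p = 4390,
                              dt_flow = 0.02, t_total = 4,
                              injection_window = c(2, 3),
                              forces = c("drag", "gravity", "brownian"),
                              gravity = NULL, alpha_p = 0,
                              cunningham = FALSE,
                              brownian_printed_form = FALSE,
                              substep_transit_frac = 1 / 20,
                              profile = c("parabolic", "plug"),
                              snapshot_times = numeric(0), seed = 1L) {
  check_positive(dt_flow, "dt_flow")
  if (n_particles < 1) stopf("'n_particles' must be >= 1")
  bad <- setdiff(forces, c("drag", "gravity", "brownian", "lift", "virtual_mass"))
  if (length(bad) > 0) stopf("unknown force(s): %s", paste(bad, collapse = ", "))
  structure(list(n_particles = as.integer(n_particles), rho_p = rho_p,
                 dt_flow = dt_flow, t_total = t_total,
                 injection_window = injection_window, forces = forces,
                 gravity = gravity, alpha_p = alpha_p,
                 cunningham = cunningham,
                 brownian_printed_form = brownian_printed_form,
                 substep_transit_frac = substep_transit_frac,
                 profile = match.arg(profile),
                 snapshot_times = snapshot_times, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Advance particles by one sub-step
#'
#' Integrates the particle momentum balance -- Schiller-Naumann drag,
#' gravity with the (1 - alpha_p) buoyancy factor, and Brownian force --
#' over `dt` with an exponential (point-implicit) drag integrator: the drag
#' rate beta is frozen at the start-of-step slip Reynolds number and the
#' resulting linear ODE is solved exactly, so the scheme is stable for any
#' dt and reduces to Euler-Maruyama for the Brownian term as beta dt -> 0
#' and to overdamped diffusion (MSD = 2 D dt) as beta dt -> infinity.
#' Optional Saffman shear lift and virtual-mass terms (both off by default)
#' enter as an explicit extra acceleration and an added-mass factor.
#'
#' @param pos n x 3 positions, m.
#' @param vel n x 3 velocities, m/s.
#' @param d_p length-n diameters, m.
#' @param u n x 3 local fluid velocities, m/s.
#' @param dt sub-step, s.
#' @param rho_p particle density(ies), kg/m^3.
#' @param air an [air_properties()].
#' @param forces force toggles as in [simulation_config()].
#' @param gravity gravity vector, m/s^2.
#' @param alpha_p particle volume fraction.
#' @param cunningham,printed_form see [simulation_config()].
#' @param shear optional length-n fluid velocity gradient magnitude (1/s)
#'   used by the Saffman lift when enabled.
#' @param lift_dir optional n x 3 unit vectors for the lift direction.
#' @return list with updated `pos` and `vel`.
#' @export
advance_particles <- function(pos, vel, d_p, u, dt, rho_p,
                              air = air_properties(),
                              forces = c("drag", "gravity", "brownian"),
                              gravity = c(0, 0, -9.81), alpha_p = 0,
                              cunningham = FALSE, printed_form = FALSE,
                              shear = NULL, lift_dir = NULL) {
  n <- nrow(pos)
  if (!"drag" %in% forces) {
    # ballistic motion plus any body accelerations
    acc <- matrix(0, n, 3)
    if ("gravity" %in% forces)
      acc <- acc + matrix(gravity, n, 3, byrow = TRUE) * (1 - alpha_p)
    vel2 <- vel + acc * dt
    return(list(pos = pos + (vel + vel2) / 2 * dt, vel = vel2))
  }
  slip <- u - vel
  slip_mag <- sqrt(rowSums(slip^2))
  Re <- air$density * slip_mag * d_p / air$viscosity
  Cc <- if (cunningham) cunningham_correction(d_p) else 1
  beta <- 18 * air$viscosity / (rho_p * d_p^2) * drag_factor(Re) / Cc
  if ("virtual_mass" %in% forces)
    beta <- beta / (1 + 0.5 * air$density / rho_p)
  acc <- matrix(0, n, 3)
  if ("gravity" %in% forces)
    acc <- acc + matrix(gravity, n, 3, byrow = TRUE) * (1 - alpha_p)
  if ("brownian" %in% forces) {
    m_p <- pi / 6 * d_p^3 * rho_p
    acc <- acc + brownian_kick(d_p, air, dt, n = n,
                               printed_form = printed_form) / m_p
  }
  if ("lift" %in% forces && !is.null(shear) && !is.null(lift_dir)) {
    # Saffman shear lift, linearized: F = 1.615 d^2 sqrt(rho eta |G|) |v_s|
    m_p <- pi / 6 * d_p^3 * rho_p
    fmag <- 1.615 * d_p^2 * sqrt(air$density * air$viscosity * abs(shear)) * slip_mag
    acc <- acc + lift_dir * (fmag / m_p)
  }
  # exact solution of dv/dt = beta (u* - v) with u* = u + acc / beta
  ustar <- u + acc / beta
  ebd <- exp(-beta * dt)
  dv <- (vel - ustar)
  vel2 <- ustar + dv * ebd
  pos2 <- pos + ustar * dt + dv * (1 - ebd) / beta
  list(pos = pos2, vel = vel2)
}
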