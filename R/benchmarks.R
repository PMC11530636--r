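# Closed-form deposition benchmarks from the aerosol literature, used as
# independent oracles for the Lagrangian tracker.

#' Stokes terminal settling velocity
#'
#' v_ts = rho_p d_p^2 g / (18 eta), the low-Reynolds-number settling speed.
#'
#' @param d_p diameter, m.
#' @param rho_p particle density, kg/m^3.
#' @param air an [air_properties()].
#' @param g gravitational acceleration magnitude (default 9.81).
#' @return terminal velocity, m/s.
#' @export
stokes_terminal_velocity <- function(d_p, rho_p, air = air_properties(),
                                     g = 9.81) {
  rho_p * d_p^2 * g / (18 * air$viscosity)
}

#' Gormley-Kennedy diffusional deposition in a straight tube
#'
#' Deposition efficiency of a diffusing aerosol in fully developed laminar
#' tube flow as a function of the dimensionless deposition parameter
#' xi = pi D L / Q. Penetration P is the classical two-branch series:
#' for xi < 0.02, P = 1 - 2.5638 xi^(2/3) + 1.2 xi + 0.1767 xi^(4/3);
#' otherwise P = 0.81905 exp(-3.6568 xi) + 0.09753 exp(-22.305 xi)
#' + 0.0325 exp(-56.961 xi) + 0.01544 exp(-107.62 xi).
#'
#' @param xi deposition parameter pi D L / Q (vectorized).
#' @return deposition efficiency 1 - P.
#' @export
gormley_kennedy_efficiency <- function(xi) {
  if (any(xi < 0)) stopf("'xi' must be >= 0")
  P <- ifelse(xi < 0.02,
              1 - 2.5638 * xi^(2 / 3) + 1.2 * xi + 0.1767 * xi^(4 / 3),
              0.81905 * exp(-3.6568 * xi) + 0.09753 * exp(-22.305 * xi) +
                0.0325 * exp(-56.961 * xi) + 0.01544 * exp(-107.62 * xi))
  1 - P
}

#' Gravitational deposition in a horizontal tube (laminar flow)
#'
#' Pich's analytic efficiency for sedimentation from fully developed
#' parabolic flow in a horizontal circular tube:
#' eta = (2/pi) (2 kappa sqrt(1 - kappa^(2/3)) - kappa^(1/3)
#' sqrt(1 - kappa^(2/3)) + asin(kappa^(1/3))) with
#' kappa = 3 L v_ts / (8 R u_mean), clipped at full deposition for
#' kappa >= 1.
#'
#' @param v_ts terminal settling velocity, m/s.
#' @param L tube length, m.
#' @param R tube radius, m.
#' @param u_mean mean axial velocity, m/s.
#' @return deposition efficiency in `[0, 1]`.
#' @export
pich_sedimentation_efficiency <- function(v_ts, L, R, u_mean) {
  kappa <- 3 * L * v_ts / (8 * R * u_mean)
  kappa <- pmin(kappa, 1)
  k13 <- kappa^(1 / 3)
  s <- sqrt(pmax(1 - k13^2, 0))
  2 / pi * (2 * kappa * s - k13 * s + asin(k13))
}
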