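#' Breathing pattern
#'
#' Sinusoidal heavy-exercise respiratory cycle Q(t) = Qmax sin(2 pi t / T),
#' with t in [0, T/2] the inhalation phase (Q > 0) and [T/2, T] exhalation.
#' `waveform = "constant"` gives a steady inflow Q = Qmax (used e.g. for
#' peak-flow and validation runs).
#'
#' @param Qmax_lpm peak flow in L/min (default 90, heavy exercise).
#' @param period_s cycle period T in seconds (default 2).
#' @param waveform `"sinusoidal"` (default) or `"constant"`.
#' @return object of class `breathing_pattern`.
#' @export
breathing_pattern <- function(Qmax_lpm = 90, period_s = 2,
                              waveform = c("sinusoidal", "constant")) {
  check_positive(Qmax_lpm, "Qmax_lpm")
  check_positive(period_s, "period_s")
  waveform <- match.arg(waveform)
  structure(list(Qmax_lpm = Qmax_lpm, period_s = period_s,
                 Qmax = Qmax_lpm / 60000,   # m^3/s
                 waveform = waveform),
            class = "breathing_pattern")
}

#' Evaluate the breathing waveform
#'
#' @param t time(s), seconds, `t >= 0` (vectorized).
#' @param pattern a [breathing_pattern()].
#' @return volumetric flow in m^3/s; positive during inhalation.
#' @examples
#' p <- breathing_pattern(90, 2)
#' breathing_waveform(0.5, p) * 60000   # = 90 L/min at the sine peak
#' @export
breathing_waveform <- function(t, pattern) {
  if (any(t < 0)) stopf("'t' must be >= 0")
  if (pattern$waveform == "constant") return(rep(pattern$Qmax, length(t)))
  pattern$Qmax * sin(2 * pi * t / pattern$period_s)
}

#' Mean inhalation flow of a breathing pattern
#'
#' Mean of Q(t) over the inhalation half-cycle: (2/pi) Qmax for the
#' sinusoidal waveform, Qmax for the constant one.
#'
#' @param pattern a [breathing_pattern()].
#' @param units `"m3s"` (default) or `"lpm"`.
#' @return mean inspiratory flow.
#' @export
mean_inhalation_flow <- function(pattern, units = c("m3s", "lpm")) {
  units <- match.arg(units)
  q <- if (pattern$waveform == "constant") pattern$Qmax else 2 / pi * pattern$Qmax
  if (units == "lpm") q * 60000 else q
}

#' Air properties
#'
#' Carrier-gas constants: density 1.177 kg/m^3 and temperature 300 K by
#' default, dynamic viscosity 1.85e-5 Pa s (air at 300 K), and the
#' Boltzmann constant.
#'
#' @param density_kgm3 air density (kg/m^3).
#' @param temperature_K fluid temperature (K).
#' @param viscosity_Pas dynamic viscosity (Pa s).
#' @return object of class `air_properties`.
#' @export
air_properties <- function(density_kgm3 = 1.177, temperature_K = 300,
                           viscosity_Pas = 1.85e-5) {
  check_positive(density_kgm3, "density_kgm3")
  if (temperature_K < 0) stopf("'temperature_K' must be >= 0")
  check_positive(viscosity_Pas, "viscosity_Pas")
  structure(list(density = density_kgm3, temperature = temperature_K,
                 viscosity = viscosity_Pas, k_b = 1.380649e-23),
            class = "air_properties")
}

#' Distribute a total flow through an airway tree
#'
#' Splits the inlet flow at every junction in proportion to the Poiseuille
#' conductance of the downstream subtrees. A terminal segment has
#' conductance proportional to d^4/L; an internal segment is its own d^4/L
#' conductance in series with the parallel sum of its children's subtree
#' conductances. Flow is conserved exactly at every junction.
#'
#' @param tree an `airway_tree`.
#' @param Q_total total volumetric flow at the inlet, m^3/s (may be
#'   negative during exhalation).
#' @param profile `"parabolic"` (default) or `"plug"` velocity profile.
#' @return object of class `segment_flow`: data.frame with `id`, `Q`
#'   (m^3/s), `u_mean` (m/s) plus the profile kind.
#' @export
distribute_flow <- function(tree, Q_total, profile = c("parabolic", "plug")) {
  profile <- match.arg(profile)
  if (!is.finite(Q_total)) stopf("'Q_total' must be finite")
  s <- tree$segments
  if (any(s$diameter <= 0)) stopf("zero-diameter segment")
  len <- segment_lengths(tree)
  # d^4/L in consistent units (mm cancels in the split ratios)
  g_own <- s$diameter^4 / len
  kids <- lapply(s$id, function(i) which(!is.na(s$parent_id) & s$parent_id == i))
  G_sub <- numeric(nrow(s))
  order_by_gen <- order(s$generation, decreasing = TRUE)
  for (i in order_by_gen) {
    ch <- kids[[i]]
    G_sub[i] <- if (length(ch) == 0) g_own[i]
                else 1 / (1 / g_own[i] + 1 / sum(G_sub[ch]))
  }
  Q <- numeric(nrow(s))
  Q[is.na(s$parent_id)] <- Q_total
  for (i in order(s$generation)) {
    ch <- kids[[i]]
    if (length(ch) > 0) Q[ch] <- Q[i] * G_sub[ch] / sum(G_sub[ch])
  }
  area <- pi / 4 * (s$diameter * 1e-3)^2   # m^2
  structure(list(table = data.frame(id = s$id, Q = Q, u_mean = Q / area),
                 profile = profile),
            class = "segment_flow")
}

#' Local fluid velocity inside a segment
#'
#' Axial velocity at radial offset `r` from the segment centerline:
#' parabolic profile u = 2 u_mean (1 - (r/R)^2), or plug u = u_mean. The
#' cross-section integral of either profile equals the segment flow.
#'
#' @param tree an `airway_tree`.
#' @param flow a [distribute_flow()] result.
#' @param segment_id segment id.
#' @param r radial offset from the centerline, metres; must satisfy
#'   `0 <= r <= R` (a particle beyond the wall must already be deposited).
#' @return velocity vector (m/s) along the segment axis.
#' @export
local_velocity <- function(tree, flow, segment_id, r) {
  s <- tree$segments
  i <- match(segment_id, s$id)
  if (is.na(i)) stopf("unknown segment id %s", segment_id)
  R <- s$diameter[i] / 2 * 1e-3
  if (any(r < 0) || any(r > R))
    stopf("radial offset outside the lumen (r > R): particle should be deposited")
  u_mean <- flow$table$u_mean[match(segment_id, flow$table$id)]
  mag <- if (flow$profile == "plug") rep(u_mean, length(r))
         else 2 * u_mean * (1 - (r / R)^2)
  ax <- segment_axes(tree)[i, ]
  outer(mag, ax)
}

#' Inlet turbulence boundary conditions
#'
#' Computes the transitional k-omega SST inlet quantities from a reference
#' velocity: turbulent kinetic energy k = 3/2 (I |u_ref|)^2 (isotropic
#' turbulence), specific dissipation omega = sqrt(k) / (C_mu^0.25 L) with
#' C_mu = 0.09, turbulence percentage Tu = 100 sqrt(2k/3)/|u_ref|,
#' intermittency gamma = 1 at the inlet, and the transition momentum
#' thickness Reynolds number from [transition_re_theta()]. These values are
#' reported for solver parity; the reduced-order flow model does not consume
#' them.
#'
#' @param u_ref reference (inlet mean) velocity magnitude, m/s.
#' @param I turbulence intensity (default 0.04, i.e. 4%).
#' @param L turbulence length scale, m (e.g. the inlet diameter).
#' @param air an [air_properties()] (unused in the formulas, carried for
#'   reporting).
#' @return list of class `turbulence_bc` with `k`, `omega`, `Tu`, `gamma`,
#'   `re_theta`, `C_mu`, inputs echoed.
#' @examples
#' inlet_turbulence_bc(u_ref = 1, I = 0.04, L = 0.018)
#' @export
inlet_turbulence_bc <- function(u_ref, I = 0.04, L, air = air_properties()) {
  check_positive(u_ref, "u_ref")
  check_positive(L, "L")
  if (I < 0) stopf("'I' must be >= 0")
  C_mu <- 0.09
  k <- 3 / 2 * (I * u_ref)^2
  omega <- sqrt(k) / (C_mu^0.25 * L)
  Tu <- 100 * sqrt(2 / 3 * k) / u_ref
  structure(list(k = k, omega = omega, Tu = Tu, gamma = 1,
                 re_theta = if (Tu > 0) transition_re_theta(Tu) else NA_real_,
                 C_mu = C_mu, u_ref = u_ref, I = I, L = L),
            class = "turbulence_bc")
}

#' Transition momentum-thickness Reynolds number
#'
#' Empirical transition correlation used by the Langtry-Menter model as the
#' inlet condition for Re_theta, piecewise in the turbulence percentage Tu:
#' for Tu <= 1.3, Re_theta = 1173.51 - 589.428 Tu + 0.2196 / Tu^2; for
#' Tu > 1.3, Re_theta = 331.5 / (Tu - 0.5658)^0.671. The left branch is
#' used at the Tu = 1.3 boundary.
#'
#' @param Tu turbulence percentage, > 0 (vectorized).
#' @return Re_theta (dimensionless).
#' @examples
#' transition_re_theta(1)   # 584.3016
#' @export
transition_re_theta <- function(Tu) {
  if (any(Tu <= 0)) stopf("'Tu' must be > 0")
  ifelse(Tu <= 1.3,
         1173.51 - 589.428 * Tu + 0.2196 / Tu^2,
         331.5 / (Tu - 0.5658)^0.671)
}
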