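#' Deposition tally
#'
#' Counts and masses of particles by fate, with left/right lobar splits of
#' the deposited (stuck) fraction. `n_scape`/`m_scape` are particles that
#' escaped through the distal outlets (toward the unmodeled bronchiolar and
#' alveolar generations); `n_exhaled`/`m_exhaled` left through the inlet.
#'
#' @param n_stick,n_scape,n_exhaled,n_airborne counts.
#' @param m_stick,m_scape,m_exhaled,m_airborne masses, kg.
#' @param n_stick_L,n_stick_R,m_stick_L,m_stick_R lobar splits of the stuck
#'   particles (lobe-resolvable sticks only).
#' @return object of class `deposition_tally`.
#' @export
deposition_tally <- function(n_stick = 0, n_scape = 0, n_exhaled = 0,
                             n_airborne = 0, m_stick = 0, m_scape = 0,
                             m_exhaled = 0, m_airborne = 0,
                             n_stick_L = 0, n_stick_R = 0,
                             m_stick_L = 0, m_stick_R = 0) {
  vals <- c(n_stick, n_scape, n_exhaled, n_airborne,
            m_stick, m_scape, m_exhaled, m_airborne,
            n_stick_L, n_stick_R, m_stick_L, m_stick_R)
  if (any(vals < 0)) stopf("tally entries must be non-negative")
  if (n_stick_L + n_stick_R > n_stick + 1e-9)
    stopf("lobar stick counts exceed total sticks")
  structure(list(n_stick = n_stick, n_scape = n_scape, n_exhaled = n_exhaled,
                 n_airborne = n_airborne, n_total = n_stick + n_scape +
                   n_exhaled + n_airborne,
                 m_stick = m_stick, m_scape = m_scape, m_exhaled = m_exhaled,
                 m_airborne = m_airborne, m_total = m_stick + m_scape +
                   m_exhaled + m_airborne,
                 n_stick_L = n_stick_L, n_stick_R = n_stick_R,
                 m_stick_L = m_stick_L, m_stick_R = m_stick_R),
            class = "deposition_tally")
}

#' Build a tally from per-particle records
#'
#' @param records track records (see [write_tracks()]).
#' @return a [deposition_tally()].
#' @export
tally_from_records <- function(records) {
  m <- pi / 6 * (records$d_um * 1e-6)^3 * records$rho_p
  st <- records$status
  lob <- records$lobe
  stick <- st == "stuck"
  deposition_tally(
    n_stick = sum(stick), n_scape = sum(st == "escaped"),
    n_exhaled = sum(st == "exhaled"), n_airborne = sum(st == "airborne"),
    m_stick = sum(m[stick]), m_scape = sum(m[st == "escaped"]),
    m_exhaled = sum(m[st == "exhaled"]), m_airborne = sum(m[st == "airborne"]),
    n_stick_L = sum(stick & lob == "left", na.rm = TRUE),
    n_stick_R = sum(stick & lob == "right", na.rm = TRUE),
    m_stick_L = sum(m[stick & lob == "left"], na.rm = TRUE),
    m_stick_R = sum(m[stick & lob == "right"], na.rm = TRUE))
}

#' Metrics configuration
#'
#' @param icrp_correction fraction in `[0, 1]` of escaped particles credited
#'   as deposited in the unmodeled bronchiolar/alveolar generations (ICRP
#'   Publication 130 style correction). Required: there is no defensible
#'   default, so it must be supplied explicitly.
#' @param mdf_convention `"printed"` (default): mDF = (m_stick + m_scape) /
#'   m_total with exhaled mass tracked separately and excluded from the
#'   numerator; `"corrected"`: the escaped mass is weighted by
#'   `icrp_correction`, symmetric with the number-based fraction.
#' @param histogram_bins,histogram_range size-histogram layout (defaults: 19
#'   bins on 0-10 um).
#' @return object of class `metrics_config`.
#' @export
metrics_config <- function(icrp_correction,
                           mdf_convention = c("printed", "corrected"),
                           histogram_bins = 19,
                           histogram_range = c(0, 10)) {
  if (missing(icrp_correction) || is.null(icrp_correction))
    stopf("'icrp_correction' must be given explicitly (fraction in [0, 1])")
  if (icrp_correction < 0 || icrp_correction > 1)
    stopf("'icrp_correction' must lie in [0, 1]")
  structure(list(icrp_correction = icrp_correction,
                 mdf_convention = match.arg(mdf_convention),
                 histogram_bins = histogram_bins,
                 histogram_range = histogram_range),
            class = "metrics_config")
}

#' Number deposition fraction
#'
#' nDF = (n_stick + n_scape * icrp_correction) / n_total.
#'
#' @param tally a [deposition_tally()].
#' @param config a [metrics_config()].
#' @return fraction in `[0, 1]`.
#' @export
ndf <- function(tally, config) {
  if (!inherits(config, "metrics_config")) stopf("'config' must be a metrics_config")
  if (tally$n_total <= 0) stopf("empty tally: n_total must be > 0")
  (tally$n_stick + tally$n_scape * config$icrp_correction) / tally$n_total
}

#' Mass deposition fraction
#'
#' Under the `"printed"` convention, mDF = (m_stick + m_scape) / m_total
#' with the exhaled mass excluded from the numerator; under `"corrected"`,
#' mDF = (m_stick + m_scape * icrp_correction) / m_total.
#'
#' @inheritParams ndf
#' @return fraction in `[0, 1]`.
#' @export
mdf <- function(tally, config) {
  if (!inherits(config, "metrics_config")) stopf("'config' must be a metrics_config")
  if (tally$m_total <= 0) stopf("empty tally: m_total must be > 0")
  w <- if (config$mdf_convention == "printed") 1 else config$icrp_correction
  (tally$m_stick + tally$m_scape * w) / tally$m_total
}

#' Regional (lobar) deposition fractions
#'
#' Left/right splits of the deposited particles:
#' mDF_L = m_stick_L / (m_stick_L + m_stick_R), likewise for the right lobe
#' and for counts. The pairs always sum to one.
#'
#' @param tally a [deposition_tally()] with lobe-resolved sticks.
#' @return list with `mdf_L`, `mdf_R`, `ndf_L`, `ndf_R`.
#' @export
regional_fractions <- function(tally) {
  mt <- tally$m_stick_L + tally$m_stick_R
  nt <- tally$n_stick_L + tally$n_stick_R
  if (mt <= 0 || nt <= 0)
    stopf("no lobe-resolved deposition: regional fractions undefined")
  list(mdf_L = tally$m_stick_L / mt, mdf_R = tally$m_stick_R / mt,
       ndf_L = tally$n_stick_L / nt, ndf_R = tally$n_stick_R / nt)
}

#' Impaction parameter
#'
#' d_p^2 Q with d_p in um and Q in L/min (um^2 L/min), the
#' geometry-independent abscissa used to compare deposition-efficiency
#' curves across studies.
#'
#' @param d_um particle diameter, um.
#' @param Q_lpm volumetric flow, L/min (for a waveform, the mean inspiratory
#'   flow; see [mean_inhalation_flow()]).
#' @return impaction parameter(s).
#' @export
impaction_parameter <- function(d_um, Q_lpm) {
  check_positive(d_um, "d_um")
  check_positive(Q_lpm, "Q_lpm")
  d_um^2 * Q_lpm
}

#' Deposition-efficiency curve over the impaction parameter
#'
#' Builds the (d_p^2 Q, efficiency) curve from per-size sweep results and
#' applies the exclusion filter d_p^2 Q < 0.1 (points below the threshold
#' are dropped; the threshold itself is retained). When a
#' [breathing_pattern()] is supplied instead of a scalar flow, Q is its mean
#' inspiratory flow.
#'
#' @param d_um particle diameters, um.
#' @param efficiency deposition efficiencies in `[0, 1]`, same length.
#' @param Q scalar flow in L/min, or a [breathing_pattern()].
#' @param threshold exclusion threshold (default 0.1 um^2 L/min).
#' @return data.frame with `d_um`, `impaction_parameter`, `efficiency`,
#'   sorted by the impaction parameter.
#' @export
impaction_curve <- function(d_um, efficiency, Q, threshold = 0.1) {
  if (length(d_um) != length(efficiency))
    stopf("'d_um' and 'efficiency' must have the same length")
  Q_lpm <- if (inherits(Q, "breathing_pattern"))
    mean_inhalation_flow(Q, units = "lpm") else Q
  ip <- impaction_parameter(d_um, Q_lpm)
  keep <- ip >= threshold
  out <- data.frame(d_um = d_um[keep], impaction_parameter = ip[keep],
                    efficiency = efficiency[keep])
  out[order(out$impaction_parameter), , drop = FALSE]
}

#' Normalized particle-size histogram
#'
#' Equal-width density histogram of an airborne-size snapshot: 19 bins on
#' 0-10 um by default, normalized so the densities integrate to one.
#' Diameters outside the range are dropped (with a note in the result).
#'
#' @param d_um airborne particle diameters at the snapshot time, um.
#' @param config a [metrics_config()].
#' @return data.frame with `bin_lo`, `bin_hi`, `mid`, `count`, `density`.
#' @export
size_histogram <- function(d_um, config) {
  if (length(d_um) == 0) stopf("empty snapshot: no airborne particles")
  rng <- config$histogram_range
  nb <- config$histogram_bins
  br <- seq(rng[1], rng[2], length.out = nb + 1)
  inside <- d_um >= rng[1] & d_um <= rng[2]
  h <- graphics::hist(d_um[inside], breaks = br, plot = FALSE)
  data.frame(bin_lo = br[-(nb + 1)], bin_hi = br[-1],
             mid = h$mids, count = h$counts,
             density = h$counts / sum(h$counts) / diff(br)[1])
}

#' Read a deposition summary table
#'
#' Reads a CSV with columns `geometry`, `mdf`, `ndf`, `mdf_L`, `mdf_R`,
#' `ndf_L`, `ndf_R` (percent) and checks that each row's regional pairs sum
#' to 100 within the stated rounding tolerance.
#'
#' @param path CSV file; defaults to the deposition summary for the eight
#'   phenotype geometries shipped with the package.
#' @param tol_pp allowed deviation of regional sums from 100, percentage
#'   points (default 0.6).
#' @return data.frame of the table.
#' @export
read_deposition_table <- function(path = system.file("extdata",
                                                     "deposition_summary.csv",
                                                     package = "aerodose"),
                                  tol_pp = 0.6) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("geometry", "mdf", "ndf", "mdf_L", "mdf_R", "ndf_L", "ndf_R")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stopf("summary table missing column(s): %s", paste(miss, collapse = ", "))
  bad <- abs(tab$mdf_L + tab$mdf_R - 100) > tol_pp |
         abs(tab$ndf_L + tab$ndf_R - 100) > tol_pp
  if (any(bad))
    stopf("regional fractions of row(s) %s do not sum to 100%%",
          paste(tab$geometry[bad], collapse = ", "))
  tab
}
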