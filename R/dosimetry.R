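#' Iodine-131 nuclide data
#'
#' Emission data used for the point-source decks: beta endpoint energies
#' 0.606 MeV (89.6%), 0.334 MeV (7.34%) and 0.807 MeV (0.39%); principal
#' gamma line 0.364 MeV (81.5%); half-life 8.02 days; specific activity of
#' the pure nuclide 4.6e15 Bq/kg; default airborne mass fraction 0.21%.
#'
#' @return object of class `nuclide_data`.
#' @export
nuclide_i131 <- function() {
  structure(list(
    name = "I-131",
    half_life_days = 8.02,
    beta = data.frame(energy_MeV = c(0.606, 0.334, 0.807),
                      intensity_pct = c(89.6, 7.34, 0.39)),
    gamma = data.frame(energy_MeV = 0.364, intensity_pct = 81.5),
    pure_specific_activity = 4.6e15,   # Bq/kg
    mass_fraction = 0.0021),
    class = "nuclide_data")
}

#' Effective specific activity of an aerosol
#'
#' Specific activity of airborne particles that contain a mass fraction of
#' the pure nuclide: the product `mass_fraction * pure_SA`. With the
#' iodine-131 defaults (0.21% of 4.6e15 Bq/kg) this is 9.66e12 Bq/kg,
#' i.e. 1e13 Bq/kg to one significant figure.
#'
#' @param mass_fraction nuclide mass fraction in the particle, in (0, 1].
#' @param pure_SA specific activity of the pure nuclide, Bq/kg.
#' @param signif_digits if non-NULL, round the result to this many
#'   significant digits for reporting.
#' @return specific activity, Bq/kg.
#' @export
effective_specific_activity <- function(mass_fraction = 0.0021,
                                        pure_SA = 4.6e15,
                                        signif_digits = NULL) {
  if (mass_fraction <= 0 || mass_fraction > 1)
    stopf("'mass_fraction' must be in (0, 1]")
  sa <- mass_fraction * pure_SA
  if (!is.null(signif_digits)) sa <- signif(sa, signif_digits)
  sa
}

#' Activity of a single particle
#'
#' A = (pi/6) d_p^3 rho_p SA: sphere mass times the effective specific
#' activity.
#'
#' @param d_um particle diameter, um.
#' @param rho_p particle density, kg/m^3.
#' @param SA effective specific activity, Bq/kg.
#' @return activity, Bq (vectorized over `d_um`).
#' @export
particle_activity <- function(d_um, rho_p = 4390, SA = effective_specific_activity()) {
  check_positive(d_um, "d_um")
  check_positive(rho_p, "rho_p")
  pi / 6 * (d_um * 1e-6)^3 * rho_p * SA
}

#' Affine transform into the phantom frame
#'
#' Applies rotation, isotropic scale and translation to a point cloud
#' (metres in, centimetres out by convention of the `scale` argument).
#' The transform must be invertible; its inverse round-trips to identity.
#'
#' @param points n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix (default identity), or a list
#'   `list(axis=, angle_deg=)`.
#' @param scale isotropic scale factor (default 1).
#' @param translation length-3 offset (default 0).
#' @return transformed n x 3 matrix.
#' @export
transform_to_phantom <- function(points, rotation = diag(3), scale = 1,
                                 translation = c(0, 0, 0)) {
  if (is.list(rotation))
    rotation <- rotation_matrix(rotation$axis, rotation$angle_deg * pi / 180)
  if (abs(det(rotation)) < 1e-12 || scale == 0)
    stopf("singular transform: rotation or scale not invertible")
  points <- as.matrix(points)
  t(rotation %*% t(points) * scale) +
    matrix(translation, nrow(points), 3, byrow = TRUE)
}

#' Invert an affine phantom transform
#'
#' @inheritParams transform_to_phantom
#' @return transformed points such that composing with
#'   [transform_to_phantom()] is the identity.
#' @export
inverse_transform_from_phantom <- function(points, rotation = diag(3),
                                           scale = 1, translation = c(0, 0, 0)) {
  if (is.list(rotation))
    rotation <- rotation_matrix(rotation$axis, rotation$angle_deg * pi / 180)
  points <- as.matrix(points)
  shifted <- points - matrix(translation, nrow(points), 3, byrow = TRUE)
  t(solve(rotation) %*% t(shifted)) / scale
}

#' Batch deposited particles into Monte-Carlo point-source decks
#'
#' Each deposited particle becomes one point source per decay mode (beta and
#' gamma for iodine-131, so two sources per location by default), with
#' activity proportional to the particle mass times the effective specific
#' activity. Sources are split into batches of at most `max_per_batch`
#' (a transport-code multi-source limit); a particle's modes are kept in the
#' same batch.
#'
#' @param records track records; only rows with `status == "stuck"` are
#'   used.
#' @param nuclide a [nuclide_i131()]-style nuclide.
#' @param max_per_batch maximum sources per batch (default 500).
#' @param modes_per_particle decay modes per deposition location (default 2).
#' @param transform optional list(rotation, scale, translation) applied to
#'   the positions (phantom frame, cm).
#' @return object of class `source_deck`: list with `batches` (each a
#'   data.frame of sources: x, y, z, activity_Bq, mode), `total_activity`,
#'   `n_locations`, `nuclide`.
#' @export
batch_sources <- function(records, nuclide = nuclide_i131(),
                          max_per_batch = 500, modes_per_particle = 2,
                          transform = NULL) {
  dep <- records[records$status == "stuck", , drop = FALSE]
  if (nrow(dep) == 0) stopf("no deposited particles in the records")
  if (max_per_batch < modes_per_particle)
    stopf("'max_per_batch' must be >= 'modes_per_particle'")
  SA <- effective_specific_activity(nuclide$mass_fraction,
                                    nuclide$pure_specific_activity)
  act <- particle_activity(dep$d_um, dep$rho_p, SA)
  pts <- cbind(dep$x, dep$y, dep$z) * 100   # m -> cm
  if (!is.null(transform))
    pts <- transform_to_phantom(pts, transform$rotation %||% diag(3),
                                transform$scale %||% 1,
                                transform$translation %||% c(0, 0, 0))
  modes <- c("beta", "gamma", "beta2", "gamma2")[seq_len(modes_per_particle)]
  n_loc <- nrow(dep)
  src <- data.frame(
    location = rep(seq_len(n_loc), each = modes_per_particle),
    x = rep(pts[, 1], each = modes_per_particle),
    y = rep(pts[, 2], each = modes_per_particle),
    z = rep(pts[, 3], each = modes_per_particle),
    activity_Bq = rep(act, each = modes_per_particle),
    mode = rep(modes, n_loc), stringsAsFactors = FALSE)
  loc_per_batch <- floor(max_per_batch / modes_per_particle)
  batch_of_loc <- ceiling(seq_len(n_loc) / loc_per_batch)
  batches <- split(src, batch_of_loc[src$location])
  names(batches) <- NULL
  structure(list(batches = batches,
                 n_locations = n_loc,
                 n_sources = nrow(src),
                 total_activity = sum(act),
                 modes_per_particle = modes_per_particle,
                 max_per_batch = max_per_batch,
                 nuclide = nuclide),
            class = "source_deck")
}

#' @export
print.source_deck <- function(x, ...) {
  cat(sprintf("source_deck: %d locations, %d sources in %d batch(es) (cap %d), total activity %.4g Bq\n",
              x$n_locations, x$n_sources, length(x$batches), x$max_per_batch,
              x$total_activity))
  invisible(x)
}

#' Write a source deck to plain-text input files
#'
#' Writes one deck file per batch in a documented, transport-code-inspired
#' plain-text dialect: a header, then one `source` block per point source
#' carrying the position (cm), activity weight (Bq) and the emission
#' spectrum lines of its decay mode (beta endpoint-energy/intensity
#' triplets, or the gamma line). A JSON manifest ties the batches together.
#' [read_source_deck()] parses the files back exactly.
#'
#' @param deck a [batch_sources()] result.
#' @param dir output directory (created if needed).
#' @param stem file-name stem (default `"sources"`).
#' @return paths of the written files, invisibly.
#' @export
write_source_deck <- function(deck, dir, stem = "sources") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nuc <- deck$nuclide
  spec_lines <- function(mode) {
    if (grepl("beta", mode)) {
      sprintf("  e-spectrum beta endpoint=%.6g MeV intensity=%.6g %%",
              nuc$beta$energy_MeV, nuc$beta$intensity_pct)
    } else {
      sprintf("  e-spectrum gamma line=%.6g MeV intensity=%.6g %%",
              nuc$gamma$energy_MeV, nuc$gamma$intensity_pct)
    }
  }
  paths <- character(length(deck$batches))
  for (b in seq_along(deck$batches)) {
    bt <- deck$batches[[b]]
    lines <- c(sprintf("# point-source deck batch %d/%d nuclide=%s",
                       b, length(deck$batches), nuc$name),
               sprintf("# sources=%d total-activity=%.12g Bq",
                       nrow(bt), sum(bt$activity_Bq)))
    for (i in seq_len(nrow(bt))) {
      lines <- c(lines,
                 sprintf("source id=%d mode=%s", i, bt$mode[i]),
                 sprintf("  position %.17g %.17g %.17g cm", bt$x[i], bt$y[i], bt$z[i]),
                 sprintf("  activity %.17g Bq", bt$activity_Bq[i]),
                 spec_lines(bt$mode[i]),
                 "end")
    }
    paths[b] <- file.path(dir, sprintf("%s_batch%02d.txt", stem, b))
    writeLines(lines, paths[b])
  }
  manifest <- list(nuclide = nuc$name, n_batches = length(deck$batches),
                   n_locations = deck$n_locations, n_sources = deck$n_sources,
                   modes_per_particle = deck$modes_per_particle,
                   max_per_batch = deck$max_per_batch,
                   total_activity_Bq = deck$total_activity,
                   files = basename(paths))
  mpath <- file.path(dir, sprintf("%s_manifest.json", stem))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mpath))
}

#' Read a source deck back from its manifest
#'
#' @param manifest_path path to the JSON manifest written by
#'   [write_source_deck()].
#' @return a `source_deck` equivalent to the written one.
#' @export
read_source_deck <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  batches <- lapply(man$files, function(fn) {
    lines <- readLines(file.path(dir, fn))
    hdr <- grep("^source ", lines)
    out <- lapply(hdr, function(i) {
      mode <- sub(".*mode=", "", lines[i])
      posl <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
      actl <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
      data.frame(x = as.numeric(posl[2]), y = as.numeric(posl[3]),
                 z = as.numeric(posl[4]),
                 activity_Bq = as.numeric(actl[2]),
                 mode = mode, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  total <- sum(vapply(batches, function(b) sum(b$activity_Bq), numeric(1))) /
    man$modes_per_particle
  structure(list(batches = batches,
                 n_locations = man$n_locations,
                 n_sources = man$n_sources,
                 total_activity = total,
                 modes_per_particle = man$modes_per_particle,
                 max_per_batch = man$max_per_batch,
                 nuclide = if (man$nuclide == "I-131") nuclide_i131() else man$nuclide),
            class = "source_deck")
}
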