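# Runtime geometry tables and the deposition simulation loop.

# Precompute SI-unit arrays from an airway_tree for fast per-particle queries.
tree_runtime <- function(tree) {
  s <- tree$segments
  prox <- cbind(s$px, s$py, s$pz) * 1e-3
  dist <- cbind(s$dx, s$dy, s$dz) * 1e-3
  ax <- dist - prox
  L <- sqrt(rowSums(ax^2))
  ax <- ax / L
  R <- s$diameter / 2 * 1e-3
  n <- nrow(s)
  parent <- match(s$parent_id, s$id)
  kid1 <- rep(NA_integer_, n); kid2 <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ch <- which(!is.na(parent) & parent == i)
    if (length(ch) >= 1) kid1[i] <- ch[1]
    if (length(ch) >= 2) kid2[i] <- ch[2]
  }
  # junction ball radius at the distal end: max of own and child radii
  ballR <- R
  has1 <- !is.na(kid1); ballR[has1] <- pmax(ballR[has1], R[kid1[has1]])
  has2 <- !is.na(kid2); ballR[has2] <- pmax(ballR[has2], R[kid2[has2]])
  sib <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (!is.na(p)) {
      ch <- c(kid1[p], kid2[p])
      other <- ch[!is.na(ch) & ch != i]
      if (length(other) == 1) sib[i] <- other
    }
  }
  list(prox = prox, dist = dist, axis = ax, L = L, R = R,
       parent = parent, kid1 = kid1, kid2 = kid2, sib = sib, ballR = ballR,
       terminal = is.na(kid1) & is.na(kid2), root = which(is.na(parent)),
       lobe = s$lobe, id = s$id, n = n)
}

# Axial coordinate s and radial distance r of points in given segments.
seg_coords <- function(rt, pos, seg) {
  rel <- pos - rt$prox[seg, , drop = FALSE]
  s <- rowSums(rel * rt$axis[seg, , drop = FALSE])
  r2 <- pmax(rowSums(rel^2) - s^2, 0)
  list(s = s, r = sqrt(r2))
}

#' Simulate aerosol deposition in an airway tree
#'
#' Lagrangian tracking of an aerosol through the tree under the configured
#' forces, with stick-on-contact walls, escape through the terminal outlet
#' faces and exhalation through the inlet face. The carrier flow is the
#' reduced-order model of [distribute_flow()], re-scaled every flow step
#' from the breathing waveform; within a segment the velocity profile is
#' parabolic (or plug). Particles are injected on the inlet face with
#' flux-weighted radial positions, uniformly in time over the injection
#' window. Junctions carry a spherical blending region (radius of the
#' largest adjoining tube) inside which particles keep moving with the plug
#' velocity of the nearest downstream branch; a particle that leaves the
#' lumen and every junction region sticks where it crossed the wall.
#'
#' Deterministic for a fixed `config$seed`.
#'
#' @param tree an [airway_tree()].
#' @param breathing a [breathing_pattern()].
#' @param source a [particle_source()].
#' @param config a [simulation_config()].
#' @return object of class `deposition_result`: list with `records` (one row
#'   per particle: id, t, x, y, z in m, d_um, rho_p, status, segment_id,
#'   lobe), `tally` (a [deposition_tally()]), `snapshots` (airborne
#'   diameters at the configured times) and the echoed configuration.
#' @export
simulate_deposition <- function(tree, breathing, source = particle_source(),
                                config = simulation_config()) {
  validate_airway_tree(tree)
  set.seed(config$seed)
  rt <- tree_runtime(tree)
  flow0 <- distribute_flow(tree, 1, profile = config$profile)
  frac <- flow0$table$Q           # per-segment fraction of inlet flow
  area <- pi * rt$R^2
  gravity <- config$gravity %||% (tree$gravity_axis * 9.81)
  air <- air_properties()

  N <- config$n_particles
  d_um <- sample_particle_sizes(N, source)
  d_m <- d_um * 1e-6
  w <- config$injection_window
  t_inj <- if (diff(range(w)) == 0) rep(w[1], N) else sort(stats::runif(N, w[1], w[2]))
  # flux-weighted radial position on the inlet disk
  U <- stats::runif(N)
  rho_r <- if (config$profile == "parabolic") sqrt(1 - sqrt(1 - U)) else sqrt(U)
  phi <- stats::runif(N, 0, 2 * pi)
  root <- rt$root
  e1 <- perp_vector(rt$axis[root, ]); e2 <- unit(pracma_cross(rt$axis[root, ], e1))
  r_abs <- rho_r * rt$R[root]
  pos_init <- matrix(rt$prox[root, ], N, 3, byrow = TRUE) +
    outer(r_abs * cos(phi), e1) + outer(r_abs * sin(phi), e2) +
    matrix(rt$axis[root, ], N, 3, byrow = TRUE) * (1e-4 * rt$L[root])

  pos <- matrix(NA_real_, N, 3); vel <- matrix(0, N, 3)
  seg <- rep(NA_integer_, N)
  status <- rep(-1L, N)  # -1 pending injection, 0 airborne, 1 stuck, 2 escaped, 3 exhaled
  t_event <- rep(NA_real_, N)
  next_inj <- 1L

  t <- if (diff(range(w)) == 0) w[1] else max(0, w[1] - config$dt_flow)
  snap_pending <- sort(config$snapshot_times)
  snapshots <- list()

  local_u <- function(idx) {
    sc <- seg_coords(rt, pos[idx, , drop = FALSE], seg[idx])
    um <- Q_now * frac[seg[idx]] / area[seg[idx]]
    inball <- sc$s > rt$L[seg[idx]] & !rt$terminal[seg[idx]]
    rr <- pmin(sc$r / rt$R[seg[idx]], 1)
    mag <- if (config$profile == "plug") um else 2 * um * (1 - rr^2)
    uu <- rt$axis[seg[idx], , drop = FALSE] * mag
    # beyond the distal end inside the junction ball: plug flow of the
    # nearest child carries the particle around the bend
    ib <- which(inball)
    if (length(ib) > 0) {
      si <- seg[idx][ib]
      k1 <- rt$kid1[si]; k2 <- rt$kid2[si]
      p_ib <- pos[idx, , drop = FALSE][ib, , drop = FALSE]
      c1 <- seg_coords(rt, p_ib, k1)
      use2 <- !is.na(k2)
      pick <- k1
      if (any(use2)) {
        c2 <- seg_coords(rt, p_ib[use2, , drop = FALSE], k2[use2])
        better2 <- c2$r / rt$R[k2[use2]] < (c1$r / rt$R[k1])[use2]
        pick[use2][better2] <- k2[use2][better2]
      }
      uu[ib, ] <- rt$axis[pick, , drop = FALSE] *
        (Q_now * frac[pick] / area[pick])
    }
    uu
  }

  membership <- function(p, cand) {
    ok <- !is.na(cand)
    s <- rep(NA_real_, nrow(p)); r <- rep(NA_real_, nrow(p))
    if (any(ok)) {
      sc <- seg_coords(rt, p[ok, , drop = FALSE], cand[ok])
      s[ok] <- sc$s; r[ok] <- sc$r
    }
    inside <- ok & r <= rt$R[cand] & s >= -rt$R[cand] & s <= rt$L[cand]
    list(inside = inside, s = s, r = r)
  }

  Q_now <- 0
  while (TRUE) {
    alive <- which(status == 0L)
    if (length(alive) == 0 && next_inj > N && length(snap_pending) == 0) break
    if (t >= config$t_total - 1e-12) break
    Q_now <- breathing_waveform(min(t, config$t_total), breathing)
    dt_target <- min(config$dt_flow, config$t_total - t)
    # inject particles whose time has come within this flow step
    while (next_inj <= N && t_inj[next_inj] <= t + dt_target + 1e-12) {
      i <- next_inj
      pos[i, ] <- pos_init[i, ]
      seg[i] <- root
      status[i] <- 0L
      sc0 <- seg_coords(rt, pos[i, , drop = FALSE], root)
      um0 <- Q_now * frac[root] / area[root]
      vel[i, ] <- rt$axis[root, ] *
        (if (config$profile == "plug") um0
         else 2 * um0 * (1 - (sc0$r / rt$R[root])^2))
      next_inj <- i + 1L
    }
    alive <- which(status == 0L)
    if (length(alive) > 0) {
      # asynchronous per-particle sub-stepping: every particle consumes the
      # flow step with its own transit-limited sub-step, so a particle in a
      # fast narrow segment does not throttle the whole population
      remaining <- numeric(N)
      remaining[alive] <- dt_target
      repeat {
        act <- which(status == 0L & remaining > 1e-15)
        if (length(act) == 0) break
        uu <- local_u(act)
        # sub-step from the particle's own speed and local fluid speed, so a
        # slow near-wall particle is not throttled by its segment's peak flow
        vch <- pmax(sqrt(rowSums(vel[act, , drop = FALSE]^2)),
                    sqrt(rowSums(uu^2)), 1e-3)
        dt_i <- pmin(remaining[act],
                     config$substep_transit_frac * rt$L[seg[act]] / vch)
        brownian_on <- "brownian" %in% config$forces
        if (brownian_on) {
          # cap so one diffusive step resolves the distance to the wall
          # (otherwise first-passage wall hits are systematically missed)
          D <- air$k_b * air$temperature / (3 * pi * air$viscosity * d_m[act])
          sc_act <- seg_coords(rt, pos[act, , drop = FALSE], seg[act])
          d_wall <- pmax(rt$R[seg[act]] - sc_act$r, 0.02 * rt$R[seg[act]])
          dt_i <- pmin(dt_i, (0.3 * d_wall)^2 / (2 * D))
        }
        st <- advance_particles(pos[act, , drop = FALSE],
                                vel[act, , drop = FALSE],
                                d_m[act], uu, dt_i, config$rho_p,
                                air = air, forces = config$forces,
                                gravity = gravity, alpha_p = config$alpha_p,
                                cunningham = config$cunningham,
                                printed_form = config$brownian_printed_form)
        if (any(!is.finite(st$pos)))
          stopf("simulation aborted: non-finite particle state at t = %.4f s", t)
        pos[act, ] <- st$pos; vel[act, ] <- st$vel
        remaining[act] <- remaining[act] - dt_i
        t_now <- t + dt_target - mean(remaining[act])
        # --- relocate / classify (vectorized over boundary crossers) ---
        cur <- seg[act]
        m0 <- membership(pos[act, , drop = FALSE], cur)
        if (brownian_on) {
          # Brownian-bridge first-passage correction: a path whose endpoints
          # both lie inside the lumen may still have touched the wall during
          # the step, with probability exp(-d0 d1 / (D dt)) for wall
          # distances d0, d1 (1-D absorbing-boundary bridge)
          stay <- m0$inside & m0$s >= 0 & m0$r < rt$R[cur]
          if (any(stay)) {
            d0 <- pmax(rt$R[cur] - sc_act$r, 0)
            d1 <- pmax(rt$R[cur] - m0$r, 0)
            p_hit <- ifelse(stay, exp(-d0 * d1 / (D * dt_i)), 0)
            hitb <- stats::runif(length(act)) < p_hit
            if (any(hitb)) {
              gb <- act[hitb]
              status[gb] <- 1L
              t_event[gb] <- t + dt_target - remaining[gb]
            }
          }
        }
        # the short s < 0 entry zone is legitimate while traversing an elbow,
        # except at the inlet where crossing the face means exhalation
        out <- !m0$inside | (cur == root & m0$s < 0)
        if (any(out)) {
          oi <- which(out)
          gi <- act[oi]                       # global indices
          si <- cur[oi]
          p_out <- pos[gi, , drop = FALSE]
          esc <- m0$s[oi] > rt$L[si] & rt$terminal[si]
          exh <- m0$s[oi] < 0 & si == root
          status[gi[esc]] <- 2L; t_event[gi[esc]] <- t_now
          status[gi[exh]] <- 3L; t_event[gi[exh]] <- t_now
          rest <- which(!esc & !exh)
          if (length(rest) > 0) {
            gr <- gi[rest]; sr <- si[rest]
            pr <- p_out[rest, , drop = FALSE]
            bestq <- rep(Inf, length(gr))
            best <- rep(NA_integer_, length(gr))
            for (cand in list(rt$kid1[sr], rt$kid2[sr], rt$parent[sr],
                              rt$sib[sr])) {
              mc <- membership(pr, cand)
              q <- ifelse(mc$inside, mc$r / rt$R[cand], Inf)
              upd <- q < bestq
              best[upd] <- cand[upd]; bestq[upd] <- q[upd]
            }
            hit <- !is.na(best)
            seg[gr[hit]] <- best[hit]
            lost <- which(!hit)
            if (length(lost) > 0) {
              # beyond the distal end but not in a child: the elbow gap is a
              # blending ball in which the particle keeps moving; anywhere
              # else the tube wall is real and the particle sticks on contact
              gl <- gr[lost]; sl <- sr[lost]
              pl <- pr[lost, , drop = FALSE]
              past_end <- m0$s[oi][rest][lost] > rt$L[sl]
              d_own <- sqrt(rowSums((pl - rt$dist[sl, , drop = FALSE])^2))
              inball <- past_end & d_own <= rt$ballR[sl]
              wall <- gl[!inball]
              status[wall] <- 1L; t_event[wall] <- t_now
            }
          }
        }
      }
    }
    t <- t + dt_target
    while (length(snap_pending) > 0 && t >= snap_pending[1] - 1e-9) {
      a <- which(status == 0L)
      if (length(a) > 0)
        snapshots[[length(snapshots) + 1L]] <-
          data.frame(time = snap_pending[1], d_um = d_um[a])
      snap_pending <- snap_pending[-1]
    }
  }

  status_chr <- c("airborne", "stuck", "escaped", "exhaled")[pmax(status, 0L) + 1L]
  status_chr[status == -1L] <- "airborne"  # never injected (t_total reached)
  records <- data.frame(
    id = seq_len(N),
    t = ifelse(is.na(t_event), t, t_event),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    d_um = d_um, rho_p = config$rho_p,
    status = status_chr,
    segment_id = ifelse(is.na(seg), NA_integer_, rt$id[seg]),
    lobe = ifelse(is.na(seg), NA_character_, rt$lobe[seg]),
    stringsAsFactors = FALSE)
  structure(list(records = records,
                 tally = tally_from_records(records),
                 snapshots = if (length(snapshots) > 0) do.call(rbind, snapshots)
                             else NULL,
                 config = config, breathing = breathing, source = source),
            class = "deposition_result")
}

#' @export
print.deposition_result <- function(x, ...) {
  tl <- x$tally
  cat(sprintf("deposition_result: %d particles (stuck %d, escaped %d, exhaled %d, airborne %d)\n",
              tl$n_total, tl$n_stick, tl$n_scape, tl$n_exhaled, tl$n_airborne))
  invisible(x)
}

#' Write / read particle track records
#'
#' CSV exchange format consumed by the dosimetry exporter: columns id, t,
#' x, y, z (m), d_um, rho_p, status, segment_id, lobe.
#'
#' @param records the `records` data.frame of a `deposition_result`.
#' @param path CSV path.
#' @return `path` (write) or the records data.frame (read).
#' @export
write_tracks <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "t", "x", "y", "z", "d_um", "rho_p", "status",
            "segment_id", "lobe")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0)
    stopf("track file is missing column(s): %s", paste(miss, collapse = ", "))
  rec
}
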