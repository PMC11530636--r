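#' Write an airway tree to JSON
#'
#' Serializes the segment table and gravity axis under the versioned schema
#' `"airway-tree/1"` (units: mm). [read_tree()] is the exact inverse.
#'
#' @param tree an `airway_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  validate_airway_tree(tree)
  obj <- list(schema = "airway-tree/1", units = "mm",
              gravity_axis = tree$gravity_axis,
              segments = tree$segments)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read an airway tree from JSON
#'
#' @param path file written by [write_tree()] (schema `"airway-tree/1"`).
#' @return An [airway_tree()].
#' @export
read_tree <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stopf("malformed tree JSON: %s", conditionMessage(e)))
  for (field in c("schema", "units", "gravity_axis", "segments")) {
    if (is.null(obj[[field]]))
      stopf("tree JSON is missing required field '%s'", field)
  }
  if (!identical(obj$schema, "airway-tree/1"))
    stopf("unsupported tree schema '%s'", obj$schema)
  seg <- as.data.frame(obj$segments)
  seg$parent_id <- suppressWarnings(as.integer(seg$parent_id))
  seg$id <- as.integer(seg$id)
  seg$generation <- as.integer(seg$generation)
  airway_tree(seg, gravity_axis = as.numeric(obj$gravity_axis))
}

# ---- triangle meshes -------------------------------------------------------

#' Triangulated tube surface of an airway tree
#'
#' Builds a watertight triangle mesh: each segment becomes a closed cylinder
#' (side wall plus two end-cap fans). Caps internal to the tree are retained,
#' so the mesh is a union of closed per-segment surfaces -- watertight and
#' suitable for volume/area integrals and STL export.
#'
#' @param tree an `airway_tree`.
#' @param n_theta number of circumferential facets per ring (default 24).
#' @param axial_step axial ring spacing as a fraction of the segment
#'   diameter (default 0.5); controls the vertex density along the tube.
#' @return list with `vertices` (n x 3, mm) and `faces` (m x 3, 1-based,
#'   counter-clockwise outward), class `tri_mesh`.
#' @export
tree_to_mesh <- function(tree, n_theta = 24, axial_step = 0.5) {
  validate_airway_tree(tree)
  s <- tree$segments
  axes <- segment_axes(tree)
  lens <- segment_lengths(tree)
  verts <- list(); faces <- list(); off <- 0L
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  for (i in seq_len(nrow(s))) {
    ax <- axes[i, ]; e1 <- perp_vector(ax); e2 <- unit(pracma_cross(ax, e1))
    R <- s$diameter[i] / 2
    p <- c(s$px[i], s$py[i], s$pz[i]); d <- c(s$dx[i], s$dy[i], s$dz[i])
    nseg <- max(1L, ceiling(lens[i] / (axial_step * s$diameter[i])))
    fracs <- seq(0, 1, length.out = nseg + 1)
    ring <- function(cen) t(vapply(th, function(a) cen + R * (cos(a) * e1 + sin(a) * e2),
                                   numeric(3)))
    rings <- lapply(fracs, function(fr) ring(p + fr * (d - p)))
    v <- rbind(do.call(rbind, rings), p, d)
    nr <- nseg + 1L
    ic <- nr * n_theta + 1L; jc <- nr * n_theta + 2L
    f <- list()
    for (jr in seq_len(nseg)) {
      o1 <- (jr - 1L) * n_theta; o2 <- jr * n_theta
      for (k in seq_len(n_theta)) {
        k2 <- if (k == n_theta) 1L else k + 1L
        f[[length(f) + 1L]] <- c(o1 + k, o2 + k2, o2 + k)
        f[[length(f) + 1L]] <- c(o1 + k, o1 + k2, o2 + k2)
      }
    }
    ol <- (nr - 1L) * n_theta
    for (k in seq_len(n_theta)) {
      k2 <- if (k == n_theta) 1L else k + 1L
      # proximal cap (normal opposing axis) and distal cap (along axis)
      f[[length(f) + 1L]] <- c(ic, k2, k)
      f[[length(f) + 1L]] <- c(jc, ol + k, ol + k2)
    }
    verts[[i]] <- v
    faces[[i]] <- do.call(rbind, f) + off
    off <- off + nrow(v)
  }
  structure(list(vertices = do.call(rbind, verts),
                 faces = do.call(rbind, faces)),
            class = "tri_mesh")
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Surface area of a triangle mesh
#' @param mesh a `tri_mesh`.
#' @return total area in the square of the mesh length unit.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]; b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a triangle mesh (divergence theorem)
#' @param mesh a watertight `tri_mesh` with outward-oriented faces.
#' @return enclosed volume in the cube of the mesh length unit.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], ]; p2 <- v[f[, 2], ]; p3 <- v[f[, 3], ]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Watertightness check
#'
#' A closed orientable triangle mesh uses every undirected edge exactly
#' twice, once per direction.
#'
#' @param mesh a `tri_mesh`.
#' @return logical.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  dkey <- paste(e[, 1], e[, 2])
  all(cnt == 2) && !anyDuplicated(dkey)
}

#' Write a triangle mesh as STL
#'
#' @param mesh a `tri_mesh`.
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nn <- sqrt(rowSums(nrm^2)); nn[nn == 0] <- 1
  nrm <- nrm / nn
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    dat <- t(cbind(nrm, p1, p2, p3))
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid airway", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", p1[i, 1], p1[i, 2], p1[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", p2[i, 1], p2[i, 2], p2[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", p3[i, 1], p3[i, 2], p3[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid airway", con)
  }
  invisible(path)
}

#' Read an STL surface (binary or ASCII)
#'
#' Vertices are merged exactly; the result can be checked with
#' [mesh_is_watertight()].
#'
#' @param path STL file.
#' @return a `tri_mesh`.
#' @export
read_stl <- function(path) {
  head <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head), "solid")
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0 || nrow(tri) %% 3 != 0)
    stopf("malformed STL: no complete triangles parsed")
  key <- apply(round(tri, 9), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  structure(list(vertices = verts, faces = faces), class = "tri_mesh")
}

read_stl_ascii <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0) stopf("malformed ASCII STL: no vertex lines")
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  do.call(rbind, nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(nf) || nf <= 0) stopf("malformed binary STL header")
  out <- matrix(NA_real_, nrow = 3 * nf, ncol = 3)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    if (length(vals) < 12) stopf("malformed binary STL: truncated facet %d", i)
    readBin(con, "raw", n = 2)
    out[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  out
}

# ---- centerline extraction -------------------------------------------------

#' Skeletonize a tube surface into an airway tree
#'
#' Extracts a centerline tree from a tube-like triangulated surface by
#' geodesic level sets: mesh vertices are binned by geodesic (graph)
#' distance from the inlet, connected components of each bin form
#' cross-section rings, ring centroids become centerline nodes and component
#' adjacency across bins gives the branching topology. Chains of nodes are
#' collapsed into straight segments between topological events. The
#' estimated radius of a ring is the mean distance of its vertices to the
#' centroid.
#'
#' This works for surfaces whose cross sections are simply connected rings
#' (tube networks such as the meshes produced by [tree_to_mesh()]); it is
#' not a general-purpose medial-axis algorithm.
#'
#' @param mesh a `tri_mesh` in mm.
#' @param inlet_point 3-vector near the inlet end (defaults to the vertex
#'   with maximal z).
#' @param n_bins number of geodesic bins; the default (`NULL`) picks a bin
#'   width about one tube radius, estimated from the surface area and the
#'   geodesic extent (too-fine bins fragment cross sections into arcs).
#' @param gravity_axis passed through to the resulting tree.
#' @return An [airway_tree()] approximating the tube skeleton.
#' @export
skeletonize_surface <- function(mesh, inlet_point = NULL, n_bins = NULL,
                                gravity_axis = c(0, 0, -1)) {
  v <- mesh$vertices; f <- mesh$faces
  e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  w <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  if (is.null(inlet_point)) inlet_point <- v[which.max(v[, 3]), ]
  src <- which.min(colSums((t(v) - inlet_point)^2))
  # meshes assembled from closed per-segment tubes are geometrically
  # overlapping but graph-disconnected; bridge components through their
  # closest vertex pairs so geodesic distances span the whole conduit
  comp0 <- igraph::components(g)$membership
  while (max(comp0) > 1) {
    inA <- comp0 == comp0[src]
    ia <- which(inA); ib <- which(!inA)
    # nearest pair between the inlet component and the rest
    best <- c(NA, NA, Inf)
    for (chunk in split(ib, ceiling(seq_along(ib) / 2000))) {
      dmat <- outer(rowSums(v[ia, , drop = FALSE]^2),
                    rowSums(v[chunk, , drop = FALSE]^2), "+") -
        2 * v[ia, , drop = FALSE] %*% t(v[chunk, , drop = FALSE])
      m <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      if (dmat[m[1], m[2]] < best[3])
        best <- c(ia[m[1]], chunk[m[2]], dmat[m[1], m[2]])
    }
    g <- igraph::add_edges(g, c(best[1], best[2]),
                           attr = list(weight = sqrt(max(best[3], 0))))
    e <- rbind(e, best[1:2])   # node adjacency must see the bridges too
    comp0 <- igraph::components(g)$membership
  }
  dist <- as.numeric(igraph::distances(g, v = src)[1, ])
  if (any(!is.finite(dist))) stopf("surface is not connected")
  if (is.null(n_bins)) {
    r_est <- mesh_area(mesh) / (2 * pi * max(dist))
    n_bins <- max(8L, round(max(dist) / r_est))
  }
  br <- seq(0, max(dist), length.out = n_bins + 1)
  bin <- pmin(findInterval(dist, br, rightmost.closed = TRUE), n_bins)
  nodes <- list()   # per node: centroid, radius, bin, vertex ids
  memb <- integer(nrow(v))
  for (b in seq_len(n_bins)) {
    vb <- which(bin == b)
    if (length(vb) == 0) next
    sub <- igraph::induced_subgraph(g, vb)
    comp <- igraph::components(sub)$membership
    for (ci in seq_len(max(comp))) {
      ids <- vb[comp == ci]
      cen <- colMeans(v[ids, , drop = FALSE])
      rad <- mean(sqrt(colSums((t(v[ids, , drop = FALSE]) - cen)^2)))
      # skip degenerate components (e.g. isolated end-cap centre vertices)
      if (length(ids) < 4 || rad <= 1e-9) next
      nodes[[length(nodes) + 1L]] <- list(cen = cen, rad = rad, bin = b, ids = ids)
      memb[ids] <- length(nodes)
    }
  }
  # vertices dropped from degenerate components (cap centres etc.) inherit
  # the membership of a graph neighbour so that node adjacency can pass
  # through them
  repeat {
    orphan <- which(memb == 0)
    if (length(orphan) == 0) break
    changed <- FALSE
    for (side in 1:2) {
      a <- e[, side]; b <- e[, 3 - side]
      fix <- memb[a] == 0 & memb[b] != 0
      if (any(fix)) { memb[a[fix]] <- memb[b[fix]]; changed <- TRUE }
    }
    if (!changed) break
  }
  # adjacency between nodes via mesh edges: parent = the edge-connected node
  # with the largest geodesic bin below the child's bin
  nn <- length(nodes)
  parent <- rep(NA_integer_, nn)
  parent_bin <- rep(-1L, nn)
  bins <- vapply(nodes, function(x) x$bin, integer(1))
  em <- cbind(memb[e[, 1]], memb[e[, 2]])
  em <- em[em[, 1] != 0 & em[, 2] != 0 & em[, 1] != em[, 2], , drop = FALSE]
  for (k in seq_len(nrow(em))) {
    a <- em[k, 1]; bnode <- em[k, 2]
    if (bins[a] > bins[bnode]) { tmp <- a; a <- bnode; bnode <- tmp }
    if (bins[a] < bins[bnode] && bins[a] > parent_bin[bnode]) {
      parent[bnode] <- a
      parent_bin[bnode] <- bins[a]
    }
  }
  # collapse chains between topological events (root, branch points, leaves)
  nchild <- tabulate(parent[!is.na(parent)], nbins = nn)
  is_event <- is.na(parent) | nchild != 1
  # walk from each event node down chains
  seg_rows <- list(); seg_id <- 0L
  node_seg <- rep(NA_integer_, nn)
  children_of <- function(i) which(!is.na(parent) & parent == i)
  roots <- which(is.na(parent))
  queue <- list()
  for (r in roots) queue[[length(queue) + 1L]] <- list(start = r, parent_seg = NA_integer_, gen = 0L)
  while (length(queue) > 0) {
    item <- queue[[1]]; queue <- queue[-1]
    path <- item$start
    cur <- item$start
    repeat {
      ch <- children_of(cur)
      if (length(ch) != 1) break
      # stop extending if the child is itself a branch point? include then stop
      cur <- ch
      path <- c(path, cur)
      if (is_event[cur]) break
    }
    seg_id <- seg_id + 1L
    a <- nodes[[path[1]]]$cen; bpt <- nodes[[path[length(path)]]]$cen
    rad <- stats::median(vapply(nodes[path], function(x) x$rad, numeric(1)))
    seg_rows[[seg_id]] <- data.frame(
      id = seg_id, parent_id = item$parent_seg, generation = item$gen,
      px = a[1], py = a[2], pz = a[3], dx = bpt[1], dy = bpt[2], dz = bpt[3],
      diameter = 2 * rad, lobe = "central", stringsAsFactors = FALSE)
    ch <- children_of(cur)
    for (cc in ch)
      queue[[length(queue) + 1L]] <- list(start = cc, parent_seg = seg_id,
                                          gen = item$gen + 1L)
  }
  seg <- do.call(rbind, seg_rows)
  # snap child proximal points onto parent distal points
  for (i in seq_len(nrow(seg))) {
    pid <- seg$parent_id[i]
    if (!is.na(pid)) {
      j <- which(seg$id == pid)
      seg[i, c("px", "py", "pz")] <- seg[j, c("dx", "dy", "dz")]
    }
  }
  # lobe tags from generation-1 laterality (left = smaller x of midpoint)
  g1 <- which(seg$generation == 1)
  if (length(g1) == 2) {
    mx <- (seg$px[g1] + seg$dx[g1]) / 2
    left <- g1[which.min(mx)]; right <- g1[which.max(mx)]
    assign_lobe <- function(i, lab) {
      seg$lobe[i] <<- lab
      for (k in which(!is.na(seg$parent_id) & seg$parent_id == seg$id[i]))
        assign_lobe(k, lab)
    }
    assign_lobe(left, "left"); assign_lobe(right, "right")
  }
  airway_tree(seg, gravity_axis = gravity_axis)
}
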