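#' Airway tree objects
#'
#' An `airway_tree` is a skeleton representation of the lower human
#' respiratory tract (HRT): an ordered table of straight circular tube
#' segments, each with a proximal and a distal point (mm), a constant
#' diameter (mm), a generation index (0 = trachea) and a lobe tag.
#' Non-terminal segments normally carry exactly two children (a bifurcating
#' tree); serial chains (single children) are also permitted so that bent
#' conduits such as the mouth-throat surrogate can be expressed as a chain
#' of straight segments.
#'
#' @param segments data.frame with columns `id`, `parent_id` (NA for the
#'   root), `generation`, `px`, `py`, `pz`, `dx`, `dy`, `dz` (proximal and
#'   distal endpoints, mm), `diameter` (mm) and `lobe`
#'   (`"left"`, `"right"` or `"central"`).
#' @param gravity_axis unit 3-vector giving the direction of gravity in the
#'   tree frame (default `c(0, 0, -1)`, i.e. gravity along -z with the
#'   trachea axis also -z for an upright subject).
#'
#' @return An object of class `airway_tree`.
#' @export
airway_tree <- function(segments, gravity_axis = c(0, 0, -1)) {
  tree <- structure(
    list(segments = as.data.frame(segments),
         gravity_axis = unit(gravity_axis)),
    class = "airway_tree")
  validate_airway_tree(tree)
  tree
}

#' Validate an airway tree
#'
#' Checks the structural invariants: positive diameters and lengths, a single
#' generation-0 root, connectivity, parent/child endpoint continuity,
#' generation increments of one, and at most two children per segment.
#'
#' @param tree an `airway_tree`.
#' @return `tree`, invisibly; errors describe the first violated invariant.
#' @export
validate_airway_tree <- function(tree) {
  s <- tree$segments
  need <- c("id", "parent_id", "generation", "px", "py", "pz",
            "dx", "dy", "dz", "diameter", "lobe")
  miss <- setdiff(need, names(s))
  if (length(miss) > 0)
    stopf("segment table is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(s$id)) stopf("segment ids must be unique")
  if (any(s$diameter <= 0)) stopf("all segment diameters must be positive")
  len <- segment_lengths(tree)
  if (any(len <= 0)) stopf("all segments must have positive length")
  roots <- which(is.na(s$parent_id))
  if (length(roots) != 1) stopf("tree must have exactly one root segment")
  if (s$generation[roots] != 0) stopf("root segment must have generation 0")
  if (!all(s$lobe %in% c("left", "right", "central")))
    stopf("lobe must be one of 'left', 'right', 'central'")
  idx <- match(s$parent_id, s$id)
  child <- !is.na(s$parent_id)
  if (any(child & is.na(idx)))
    stopf("parent_id refers to a missing segment")
  if (any(s$generation[child] != s$generation[idx[child]] + 1L))
    stopf("child generation must be parent generation + 1")
  gap <- abs(cbind(s$px, s$py, s$pz)[child, , drop = FALSE] -
             cbind(s$dx, s$dy, s$dz)[idx[child], , drop = FALSE])
  if (any(gap > 1e-6))
    stopf("child proximal point must coincide with parent distal point")
  nk <- table(factor(s$parent_id[child], levels = s$id))
  if (any(nk > 2)) stopf("segments may have at most two children")
  # connectivity follows from single root + valid parent pointers (acyclic by
  # the generation increment check)
  invisible(tree)
}

segment_lengths <- function(tree) {
  s <- tree$segments
  sqrt((s$dx - s$px)^2 + (s$dy - s$py)^2 + (s$dz - s$pz)^2)
}

segment_axes <- function(tree) {
  s <- tree$segments
  a <- cbind(s$dx - s$px, s$dy - s$py, s$dz - s$pz)
  a / sqrt(rowSums(a^2))
}

root_id <- function(tree) tree$segments$id[is.na(tree$segments$parent_id)]

children_ids <- function(tree, id) {
  s <- tree$segments
  s$id[!is.na(s$parent_id) & s$parent_id == id]
}

#' Terminal (outlet) segment ids
#' @param tree an `airway_tree`.
#' @return integer vector of segment ids with no children.
#' @export
terminal_ids <- function(tree) {
  s <- tree$segments
  s$id[!(s$id %in% s$parent_id[!is.na(s$parent_id)])]
}

#' Lumen volume of an airway tree
#'
#' Sum of per-segment cylinder volumes, in cubic millimetres.
#'
#' @param tree an `airway_tree`.
#' @return volume in mm^3.
#' @export
tree_volume <- function(tree) {
  sum(pi / 4 * tree$segments$diameter^2 * segment_lengths(tree))
}

#' @export
print.airway_tree <- function(x, ...) {
  s <- x$segments
  p <- measure_tree(x)
  cat(sprintf("airway_tree: %d segments, %d generations, %d outlets\n",
              nrow(s), max(s$generation) + 1, length(terminal_ids(x))))
  cat(sprintf("  trachea diameter t_d = %.2f mm, carina angle b_a = %s\n",
              p$t_d, if (is.na(p$b_a)) "undefined" else sprintf("%.2f deg", p$b_a)))
  cat(sprintf("  lumen volume = %.0f mm^3, cumulative length = %.1f mm\n",
              p$volume, p$total_length))
  invisible(x)
}

#' Specification for a synthetic airway tree
#'
#' Parameter set for [generate_airway_tree()]. The two clinically anchoring
#' parameters are the trachea diameter `t_d` and the carina angle `b_a`
#' (angle between the two main-bronchi axes); the remaining parameters are
#' Weibel-like scaling conventions: each generation's segment diameter is
#' `diameter_ratio` times its parent's and its length is
#' `length_to_diameter` times its own diameter.
#'
#' @param t_d trachea diameter, mm.
#' @param b_a carina angle between the generation-1 bronchi, degrees,
#'   strictly inside (0, 180).
#' @param n_generations number of generations including the trachea
#'   (default 7).
#' @param diameter_ratio per-generation daughter/parent diameter ratio
#'   (default 0.78).
#' @param length_to_diameter segment length as a multiple of its diameter
#'   (default 3).
#' @param branching_angle_deg full inter-daughter angle used below the
#'   carina, degrees (default 70).
#' @param asymmetry left/right asymmetry in (0, 1): the left daughter
#'   diameter is scaled by `1 - asymmetry/2` and the right by
#'   `1 + asymmetry/2`, and branching angles are skewed by the same
#'   fraction. `0` produces a perfectly mirror-symmetric tree.
#' @param jitter relative sd of random log-normal perturbations applied to
#'   diameters and angles below generation 1 (default 0.03; set 0 for a
#'   deterministic tree). The trachea and the carina angle are never
#'   jittered so that `t_d` and `b_a` are recovered exactly.
#' @param trachea_axis unit vector of the trachea direction (default
#'   `c(0, 0, -1)`).
#' @param gravity_axis gravity direction (default `c(0, 0, -1)`).
#' @param seed integer RNG seed for the jitter.
#'
#' @return An object of class `tree_spec`.
#' @export
tree_spec <- function(t_d, b_a, n_generations = 7, diameter_ratio = 0.78,
                      length_to_diameter = 3, branching_angle_deg = 70,
                      asymmetry = 0, jitter = 0.03,
                      trachea_axis = c(0, 0, -1),
                      gravity_axis = c(0, 0, -1), seed = 1L) {
  check_positive(t_d, "t_d")
  if (!is.numeric(b_a) || b_a <= 0 || b_a >= 180)
    stopf("'b_a' must lie strictly inside (0, 180) degrees")
  if (n_generations < 1) stopf("'n_generations' must be >= 1")
  check_positive(diameter_ratio, "diameter_ratio")
  check_positive(length_to_diameter, "length_to_diameter")
  if (asymmetry < 0 || asymmetry >= 1) stopf("'asymmetry' must be in [0, 1)")
  if (jitter < 0) stopf("'jitter' must be >= 0")
  structure(list(t_d = t_d, b_a = b_a,
                 n_generations = as.integer(n_generations),
                 diameter_ratio = diameter_ratio,
                 length_to_diameter = length_to_diameter,
                 branching_angle_deg = branching_angle_deg,
                 asymmetry = asymmetry, jitter = jitter,
                 trachea_axis = unit(trachea_axis),
                 gravity_axis = unit(gravity_axis),
                 seed = as.integer(seed)),
            class = "tree_spec")
}

#' Generate a synthetic bifurcating airway tree
#'
#' Builds a parametrized analytic stand-in for a CT-reconstructed lower
#' airway: a straight trachea of diameter `t_d`, two main bronchi separated
#' by exactly the carina angle `b_a`, and further Weibel-like generations
#' with alternating branching planes. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec a [tree_spec()].
#' @return An [airway_tree()].
#' @examples
#' tr <- generate_airway_tree(tree_spec(t_d = 18.2, b_a = 97.83))
#' measure_tree(tr)
#' @export
generate_airway_tree <- function(spec) {
  if (!inherits(spec, "tree_spec")) stopf("'spec' must be a tree_spec")
  set.seed(spec$seed)
  axis0 <- spec$trachea_axis
  L0 <- spec$length_to_diameter * spec$t_d
  rows <- list(data.frame(
    id = 1L, parent_id = NA_integer_, generation = 0L,
    px = 0, py = 0, pz = 0,
    dx = axis0[1] * L0, dy = axis0[2] * L0, dz = axis0[3] * L0,
    diameter = spec$t_d, lobe = "central", stringsAsFactors = FALSE))
  next_id <- 2L
  jit <- function() if (spec$jitter > 0) exp(stats::rnorm(1, 0, spec$jitter)) else 1

  # frontier entries: id, tip position, axis, branching-plane normal,
  # diameter, generation, lobe
  p0 <- perp_vector(axis0)
  frontier <- list(list(id = 1L, tip = axis0 * L0, axis = axis0, bnorm = p0,
                        diam = spec$t_d, gen = 0L, lobe = "central"))
  for (g in seq_len(spec$n_generations - 1L)) {
    new_frontier <- list()
    for (f in frontier) {
      half <- if (f$gen == 0L) spec$b_a / 2 else spec$branching_angle_deg / 2
      skew <- if (f$gen == 0L) 0 else half * spec$asymmetry / 2
      for (side in c(-1, 1)) {
        ang <- (half + side * skew) * pi / 180
        jang <- if (f$gen == 0L) 1 else jit()
        Rm <- rotation_matrix(f$bnorm, side * ang * jang)
        ax <- unit(as.vector(Rm %*% f$axis))
        dscale <- 1 + side * spec$asymmetry / 2
        d <- f$diam * spec$diameter_ratio * dscale * (if (f$gen == 0L) 1 else jit())
        L <- spec$length_to_diameter * d
        tip <- f$tip + ax * L
        lobe <- if (f$gen == 0L) {
          if (side < 0) "left" else "right"
        } else f$lobe
        rows[[length(rows) + 1L]] <- data.frame(
          id = next_id, parent_id = f$id, generation = f$gen + 1L,
          px = f$tip[1], py = f$tip[2], pz = f$tip[3],
          dx = tip[1], dy = tip[2], dz = tip[3],
          diameter = d, lobe = lobe, stringsAsFactors = FALSE)
        # rotate the branching plane 90 deg each generation for a 3-D tree
        new_frontier[[length(new_frontier) + 1L]] <- list(
          id = next_id, tip = tip, axis = ax,
          bnorm = unit(as.vector(rotation_matrix(ax, pi / 2) %*% f$bnorm)),
          diam = d, gen = f$gen + 1L, lobe = lobe)
        next_id <- next_id + 1L
      }
    }
    frontier <- new_frontier
  }
  airway_tree(do.call(rbind, rows), gravity_axis = spec$gravity_axis)
}

#' Expected morphometric parameters of a tree specification
#'
#' Closed-form values of the four morphometric parameters implied by a
#' [tree_spec()] under zero jitter; used for round-trip checks against
#' [measure_tree()].
#'
#' @param spec a [tree_spec()].
#' @return list with `t_d`, `b_a`, `volume` (mm^3) and `total_length` (mm).
#' @export
expected_parameters <- function(spec) {
  # per generation g: 2^g segments; left/right diameter factors (1 -/+ a/2)
  g <- seq(0, spec$n_generations - 1L)
  a <- spec$asymmetry
  # sum over segments in generation g of d^2 and d: with mixing of left/right
  # factors, sum over branch paths of prod(factors) = ((1-a/2)+(1+a/2))^g = 2^g
  # for d; for d^2 the per-step factor sums to (1-a/2)^2+(1+a/2)^2.
  # sum over the 2^g branch paths of the product of per-step left/right
  # diameter factors (1 -/+ a/2): for d^k the per-step factor sum is
  # (1-a/2)^k + (1+a/2)^k.
  d0 <- spec$t_d
  r <- spec$diameter_ratio
  ltd <- spec$length_to_diameter
  fk <- function(k) (1 - a / 2)^k + (1 + a / 2)^k
  sum_d  <- d0   * r^g     * fk(1)^g
  sum_d3 <- d0^3 * (r^3)^g * fk(3)^g
  list(t_d = spec$t_d, b_a = spec$b_a,
       volume = sum(pi / 4 * ltd * sum_d3),
       total_length = sum(ltd * sum_d))
}

#' Measure morphometric parameters of an airway tree
#'
#' Computes the four parameters used to phenotype lower-airway geometries:
#' the volume-averaged trachea diameter `t_d` (length-weighted mean over
#' generation-0 segments), the carina angle `b_a` (angle between the two
#' generation-1 segment axes), the total lumen `volume` and the cumulative
#' bronchial `total_length`.
#'
#' @param tree an `airway_tree` with at least the trachea; the carina angle
#'   requires two generation-1 segments and is an error otherwise (unless
#'   the tree is an unbranched conduit, where `b_a` is `NA`).
#' @return list with `t_d` (mm), `b_a` (degrees), `volume` (mm^3),
#'   `total_length` (mm).
#' @export
measure_tree <- function(tree) {
  validate_airway_tree(tree)
  s <- tree$segments
  len <- segment_lengths(tree)
  g0 <- s$generation == 0
  t_d <- sum(s$diameter[g0] * len[g0]) / sum(len[g0])
  g1 <- which(s$generation == 1)
  if (length(g1) == 2) {
    ax <- segment_axes(tree)
    b_a <- vec_angle_deg(ax[g1[1], ], ax[g1[2], ])
  } else if (length(g1) <= 1 && all(table(s$parent_id[!is.na(s$parent_id)]) == 1)) {
    b_a <- NA_real_   # unbranched conduit: carina angle undefined by design
  } else {
    stopf("carina angle undefined: tree has %d generation-1 segments", length(g1))
  }
  list(t_d = t_d, b_a = b_a, volume = tree_volume(tree),
       total_length = sum(len))
}
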