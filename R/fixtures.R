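#' Phenotype cluster anchors
#'
#' The nine lower-airway phenotype groups on the (trachea diameter, carina
#' angle) grid, with their mean, standard deviation and min-max range for
#' both parameters. Labels encode (t_d letter)(b_a letter) with
#' s/m/b = small/mean/big: e.g. `bs` is a big trachea diameter with a small
#' carina angle. Used as anchors for the synthetic tree and cohort
#' generators and as fixtures for the clustering tools.
#'
#' @return data.frame with columns group, b_a, b_a_sd, b_a_min, b_a_max,
#'   t_d, t_d_sd, t_d_min, t_d_max (angles in degrees, diameters in mm).
#' @export
phenotype_clusters <- function() {
  data.frame(
    group = c("bs", "bm", "bb", "mb", "mm", "ms", "sb", "sm", "ss"),
    b_a   = c(76.81, 80.9, 97.83, 95.18, 79.1, 69.23, 88.57, 82.65, 67.63),
    b_a_sd = c(2.42, 3.57, 3.53, 3.15, 3.5, 3, 3.6, 3.36, 3.2),
    b_a_min = c(71.4, 76.4, 91.6, 90.6, 73.6, 64, 81.7, 78.4, 61.4),
    b_a_max = c(81.2, 87, 104, 101, 84.5, 73.2, 93.2, 89.7, 73.1),
    t_d   = c(17, 17.3, 18.2, 17, 16.2, 14.9, 15, 14.3, 13.46),
    t_d_sd = c(0.5, 0.6, 0.3, 0.4, 0.4, 0.4, 0.5, 0.5, 0.1),
    t_d_min = c(16.2, 16.1, 17.8, 16, 15.9, 14.3, 14, 13.7, 13.4),
    t_d_max = c(17.7, 18.2, 18.6, 17.6, 16.9, 15.9, 15.8, 15.5, 13.7),
    stringsAsFactors = FALSE)
}

#' Tree specification for a phenotype cluster
#'
#' Convenience wrapper: a [tree_spec()] whose trachea diameter and carina
#' angle sit at a named cluster's anchor values.
#'
#' @param group cluster label (`"ss"` ... `"bb"`).
#' @param ... further arguments to [tree_spec()].
#' @return a `tree_spec`.
#' @export
cluster_tree_spec <- function(group, ...) {
  tab <- phenotype_clusters()
  i <- match(group, tab$group)
  if (is.na(i)) stopf("unknown cluster group '%s'", group)
  tree_spec(t_d = tab$t_d[i], b_a = tab$b_a[i], ...)
}

#' Upper-airway surrogate geometry (fixture UA-1)
#'
#' A serial-tube surrogate of the extrathoracic airway (mouth-throat): an
#' oral inlet tube, three 90-degree direction changes and a glottal
#' constriction of 6 mm hydraulic diameter. At heavy-exercise peak
#' inspiratory flow (90 L/min) the constriction velocity is about 53 m/s,
#' so 10 um unit-density particles have a Stokes number well above one and
#' the surrogate captures them by inertial impaction, mimicking the
#' filtering role of the upper respiratory tract.
#'
#' Geometry (mm): horizontal oral tube (d 20, L 80) -> 90-degree turn
#' downward (pharynx, d 14, L 60) -> 90-degree turn forward into the
#' constriction (d 6, L 20) -> 90-degree turn downward (trachea-like outlet,
#' d 16, L 80).
#'
#' @return an [airway_tree()] (chain topology; carina angle undefined).
#' @export
upper_airway_surrogate <- function() {
  seg <- function(id, parent, gen, p, d, diam)
    data.frame(id = id, parent_id = parent, generation = gen,
               px = p[1], py = p[2], pz = p[3],
               dx = d[1], dy = d[2], dz = d[3],
               diameter = diam, lobe = "central", stringsAsFactors = FALSE)
  p0 <- c(0, 0, 0)
  p1 <- c(80, 0, 0)            # oral tube along +x
  p2 <- p1 + c(0, 0, -60)      # pharynx down -z
  p3 <- p2 + c(20, 0, 0)       # constriction along +x
  p4 <- p3 + c(0, 0, -80)      # outlet down -z
  rows <- rbind(seg(1L, NA_integer_, 0L, p0, p1, 20),
                seg(2L, 1L, 1L, p1, p2, 14),
                seg(3L, 2L, 2L, p2, p3, 6),
                seg(4L, 3L, 3L, p3, p4, 16))
  airway_tree(rows, gravity_axis = c(0, 0, -1))
}
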