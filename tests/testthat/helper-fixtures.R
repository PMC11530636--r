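# Shared fixture builders (all geometry generated in code).

# single straight segment; axis and length in mm
straight_tube <- function(diameter = 2, length = 100, axis = c(1, 0, 0),
                          gravity_axis = c(0, 0, -1)) {
  d <- axis / sqrt(sum(axis^2)) * length
  airway_tree(data.frame(
    id = 1L, parent_id = NA_integer_, generation = 0L,
    px = 0, py = 0, pz = 0, dx = d[1], dy = d[2], dz = d[3],
    diameter = diameter, lobe = "central", stringsAsFactors = FALSE),
    gravity_axis = gravity_axis)
}

# trachea plus two symmetric daughters at +/- half-angle
simple_bifurcation <- function(t_d = 17, b_a = 76.81, jitter = 0) {
  generate_airway_tree(tree_spec(t_d = t_d, b_a = b_a, n_generations = 2,
                                 jitter = jitter))
}

# steady inflow at Q liters/minute
steady_breathing <- function(Q_lpm) {
  breathing_pattern(Q_lpm, 2, waveform = "constant")
}

# 9 well-separated gaussian blobs on a 3x3 grid
grid_blobs <- function(n_per = 30, sd = 0.3, seed = 2) {
  set.seed(seed)
  cent <- expand.grid(x = c(0, 5, 10), y = c(0, 5, 10))
  X <- do.call(rbind, lapply(1:9, function(i)
    cbind(stats::rnorm(n_per, cent$x[i], sd),
          stats::rnorm(n_per, cent$y[i], sd))))
  list(X = X, truth = rep(1:9, each = n_per))
}

# adjusted Rand index between two partitions (closed form from the
# contingency table; independent of any clustering package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- si * sj / comb2(n)
  (sij - expected) / ((si + sj) / 2 - expected)
}
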