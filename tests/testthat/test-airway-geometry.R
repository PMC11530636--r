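test_that("generated trees recover their specified morphometry", {
  # cluster-anchored spec: measured parameters fall inside the printed ranges
  tab <- phenotype_clusters()
  for (g in c("bb", "ms", "ss")) {
    i <- match(g, tab$group)
    tr <- generate_airway_tree(cluster_tree_spec(g, seed = 3))
    p <- measure_tree(tr)
    expect_gte(p$t_d, tab$t_d_min[i])
    expect_lte(p$t_d, tab$t_d_max[i])
    expect_gte(p$b_a, tab$b_a_min[i])
    expect_lte(p$b_a, tab$b_a_max[i])
  }
  # round-trip recovery over random specs (deterministic trees)
  set.seed(71)
  for (rep in 1:25) {
    spec <- tree_spec(t_d = runif(1, 12, 20), b_a = runif(1, 50, 110),
                      n_generations = sample(3:6, 1),
                      diameter_ratio = runif(1, 0.7, 0.85),
                      asymmetry = runif(1, 0, 0.3), jitter = 0,
                      seed = rep)
    p <- measure_tree(generate_airway_tree(spec))
    ex <- expected_parameters(spec)
    expect_lt(abs(p$t_d / ex$t_d - 1), 0.01)
    expect_lt(abs(p$b_a - ex$b_a), 0.5)
    expect_lt(abs(p$volume / ex$volume - 1), 0.01)
    expect_lt(abs(p$total_length / ex$total_length - 1), 0.01)
  }
})

test_that("zero-asymmetry trees are mirror symmetric", {
  tr <- generate_airway_tree(tree_spec(t_d = 16, b_a = 85, asymmetry = 0,
                                       jitter = 0))
  s <- tr$segments
  len <- sqrt((s$dx - s$px)^2 + (s$dy - s$py)^2 + (s$dz - s$pz)^2)
  vol <- pi / 4 * s$diameter^2 * len
  expect_equal(sum(vol[s$lobe == "left"]), sum(vol[s$lobe == "right"]),
               tolerance = 1e-12)
})

test_that("tree volume matches the independent mesh-integral oracle", {
  tr <- generate_airway_tree(tree_spec(t_d = 17, b_a = 80, n_generations = 4,
                                       jitter = 0))
  m <- tree_to_mesh(tr, n_theta = 64)
  # divergence-theorem volume of the union of per-segment closed cylinders
  expect_lt(abs(mesh_volume(m) / tree_volume(tr) - 1), 0.02)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generate_airway_tree(tree_spec(t_d = 15, b_a = 90, seed = 5))
  b <- generate_airway_tree(tree_spec(t_d = 15, b_a = 90, seed = 5))
  expect_identical(a$segments, b$segments)
  c <- generate_airway_tree(tree_spec(t_d = 15, b_a = 90, seed = 6))
  expect_false(identical(a$segments, c$segments))
})

test_that("invalid specifications and trees are rejected", {
  expect_error(tree_spec(t_d = -1, b_a = 80), "positive")
  expect_error(tree_spec(t_d = 15, b_a = 190), "b_a")
  expect_error(tree_spec(t_d = 15, b_a = 0), "b_a")
  # trachea-only tree: carina angle undefined but no error for a conduit
  expect_true(is.na(measure_tree(straight_tube())$b_a))
  # broken parent pointer
  bad <- data.frame(id = 1:2, parent_id = c(NA, 7L), generation = 0:1,
                    px = 0, py = 0, pz = c(0, -10), dx = 0, dy = 0,
                    dz = c(-10, -20), diameter = 10, lobe = "central")
  expect_error(airway_tree(bad), "missing segment")
})

test_that("constant-diameter trachea measures exactly", {
  tr <- simple_bifurcation(t_d = 17, b_a = 76.81)
  p <- measure_tree(tr)
  expect_equal(p$t_d, 17)
  expect_equal(p$b_a, 76.81, tolerance = 1e-9)
})

test_that("carina angle agrees with a dense centerline-sampling oracle", {
  set.seed(12)
  for (rep in 1:10) {
    b_a <- runif(1, 50, 120)
    tr <- generate_airway_tree(tree_spec(t_d = 16, b_a = b_a,
                                         n_generations = 3, jitter = 0.05,
                                         seed = rep))
    s <- tr$segments
    g1 <- s[s$generation == 1, ]
    # sample points densely along each generation-1 centerline near the
    # carina and fit the direction from the point cloud
    angs <- lapply(seq_len(2), function(j) {
      fr <- seq(0, 0.3, length.out = 200)
      cbind(g1$px[j] + fr * (g1$dx[j] - g1$px[j]),
            g1$py[j] + fr * (g1$dy[j] - g1$py[j]),
            g1$pz[j] + fr * (g1$dz[j] - g1$pz[j]))
    })
    dirs <- lapply(angs, function(P) {
      span <- P[nrow(P), ] - P[1, ]
      P <- sweep(P, 2, P[1, ])
      v <- svd(P)$v[, 1]
      if (sum(v * span) < 0) v <- -v   # orient proximal -> distal
      v
    })
    ca <- sum(dirs[[1]] * dirs[[2]])
    brute <- acos(min(1, max(-1, ca))) * 180 / pi
    # centerlines diverge, so the inter-branch angle equals the measured one
    expect_lt(abs(brute - measure_tree(tr)$b_a), 0.5)
  }
})
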