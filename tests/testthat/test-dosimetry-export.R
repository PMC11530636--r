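# deposited-particle record table for deck building
fake_deposits <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(id = seq_len(n), t = 1,
             x = rnorm(n) / 100, y = rnorm(n) / 100, z = rnorm(n) / 100,
             d_um = runif(n, 0.1, 5), rho_p = 4390,
             status = "stuck", segment_id = 1L, lobe = "left",
             stringsAsFactors = FALSE)
}

test_that("effective specific activity reproduces the headline value", {
  expect_equal(effective_specific_activity(0.0021, 4.6e15), 9.66e12)
  expect_equal(effective_specific_activity(0.0021, 4.6e15, signif_digits = 1),
               1e13)
  expect_equal(effective_specific_activity(1, 4.6e15), 4.6e15)
  expect_equal(effective_specific_activity(0.5, 2), 1)
  expect_error(effective_specific_activity(0), "mass_fraction")
})

test_that("particle activity is sphere mass times specific activity", {
  m <- pi / 6 * (1e-6)^3 * 4390
  expect_equal(m, 2.299e-15, tolerance = 1e-3)
  expect_equal(particle_activity(1, 4390, 1e13), m * 1e13)
  expect_equal(particle_activity(2, 4390, 1e13) / particle_activity(1, 4390, 1e13),
               8, tolerance = 1e-12)
})

test_that("phantom transform round-trips and respects linearity", {
  pts <- matrix(stats::rnorm(60), 20, 3)
  rot <- list(axis = c(0, 0, 1), angle_deg = 90)
  tp <- transform_to_phantom(pts, rot, scale = 2.5, translation = c(1, -2, 3))
  # pure 90-degree rotation maps (x, y, z) to (-y, x, z)
  tp0 <- transform_to_phantom(pts, rot)
  expect_equal(tp0, cbind(-pts[, 2], pts[, 1], pts[, 3]), tolerance = 1e-12)
  back <- inverse_transform_from_phantom(tp, rot, scale = 2.5,
                                         translation = c(1, -2, 3))
  expect_lt(max(abs(back - pts)), 1e-9)
  # centroid commutes with the affine map
  expect_equal(colMeans(tp),
               as.numeric(transform_to_phantom(t(colMeans(pts)), rot,
                                               scale = 2.5,
                                               translation = c(1, -2, 3))),
               tolerance = 1e-12)
  expect_error(transform_to_phantom(pts, matrix(0, 3, 3)), "singular")
})

test_that("source batching respects the cap and conserves activity", {
  # 1150 locations x 2 decay modes under a 500-source cap -> 5 batches
  deck <- batch_sources(fake_deposits(1150))
  expect_equal(length(deck$batches), 5)
  expect_equal(deck$n_sources, 2300)
  expect_true(all(vapply(deck$batches, nrow, numeric(1)) <= 500))
  # one location -> one batch of two sources
  d1 <- batch_sources(fake_deposits(1))
  expect_equal(length(d1$batches), 1)
  expect_equal(nrow(d1$batches[[1]]), 2)
  # 500 locations -> exactly two full batches
  d500 <- batch_sources(fake_deposits(500))
  expect_equal(vapply(d500$batches, nrow, numeric(1)), c(500, 500))
  # activity conservation against brute-force recomputation
  rec <- fake_deposits(321)
  deck2 <- batch_sources(rec)
  SA <- effective_specific_activity()
  expect_equal(deck2$total_activity,
               sum(pi / 6 * (rec$d_um * 1e-6)^3 * rec$rho_p * SA),
               tolerance = 1e-12)
  expect_equal(sum(vapply(deck2$batches,
                          function(b) sum(b$activity_Bq), numeric(1))) / 2,
               deck2$total_activity, tolerance = 1e-12)
  expect_error(batch_sources(fake_deposits(10), max_per_batch = 1), "modes")
  norec <- fake_deposits(5); norec$status <- "escaped"
  expect_error(batch_sources(norec), "no deposited")
})

test_that("deck files round-trip and carry the emission spectra", {
  deck <- batch_sources(fake_deposits(1150))
  dir <- withr::local_tempdir()
  files <- write_source_deck(deck, dir)
  man <- files[length(files)]
  deck2 <- read_source_deck(man)
  expect_equal(length(deck2$batches), length(deck$batches))
  expect_equal(deck2$n_locations, deck$n_locations)
  expect_equal(deck2$total_activity, deck$total_activity, tolerance = 1e-12)
  for (b in seq_along(deck$batches)) {
    want <- deck$batches[[b]][, c("x", "y", "z", "activity_Bq", "mode")]
    rownames(want) <- NULL
    expect_equal(deck2$batches[[b]], want)
  }
  txt <- readLines(files[1])
  # gamma line 0.364 MeV at 81.5%, beta endpoints with their intensities
  expect_true(any(grepl("gamma line=0.364 MeV intensity=81.5", txt)))
  expect_true(any(grepl("beta endpoint=0.606 MeV intensity=89.6", txt)))
  expect_true(any(grepl("beta endpoint=0.334 MeV intensity=7.34", txt)))
  expect_true(any(grepl("beta endpoint=0.807 MeV intensity=0.39", txt)))
})
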