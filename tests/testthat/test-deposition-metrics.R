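test_that("number deposition fraction applies the escape credit", {
  tl <- deposition_tally(n_stick = 40, n_scape = 30, n_exhaled = 30,
                         m_stick = 1, m_scape = 1, m_exhaled = 1)
  expect_equal(ndf(tl, metrics_config(icrp_correction = 0.2)), 0.46)
  expect_equal(ndf(tl, metrics_config(icrp_correction = 1)), 0.70)
  expect_equal(ndf(tl, metrics_config(icrp_correction = 0)), 0.40)
  # monotone in the correction
  cs <- seq(0, 1, by = 0.1)
  vals <- vapply(cs, function(c) ndf(tl, metrics_config(icrp_correction = c)),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
  # the correction has no default
  expect_error(metrics_config(), "icrp_correction")
  expect_error(metrics_config(icrp_correction = 1.2), "\\[0, 1\\]")
})

test_that("mass deposition fraction supports both numerator conventions", {
  tl <- deposition_tally(n_stick = 3, n_scape = 1, n_exhaled = 1,
                         m_stick = 3e-12, m_scape = 1e-12, m_exhaled = 1e-12)
  expect_equal(mdf(tl, metrics_config(icrp_correction = 0.5)), 0.8)
  expect_equal(mdf(tl, metrics_config(icrp_correction = 0.5,
                                      mdf_convention = "corrected")), 0.7)
  # all mass stuck
  tl1 <- deposition_tally(n_stick = 5, m_stick = 2e-12)
  expect_equal(mdf(tl1, metrics_config(icrp_correction = 0)), 1)
})

test_that("regional fractions sum to one and match record replay", {
  tl <- deposition_tally(n_stick = 10, m_stick = 5e-12,
                         n_stick_L = 4, n_stick_R = 6,
                         m_stick_L = 2e-12, m_stick_R = 3e-12)
  rf <- regional_fractions(tl)
  expect_equal(rf$mdf_L + rf$mdf_R, 1)
  expect_equal(rf$ndf_L + rf$ndf_R, 1)
  expect_equal(rf$ndf_L, 0.4)
  expect_error(regional_fractions(deposition_tally(n_stick = 1, m_stick = 1)),
               "undefined")
  # replay from simulated records
  tr <- simple_bifurcation()
  cfg <- simulation_config(n_particles = 800, seed = 6)
  res <- simulate_deposition(tr, breathing_pattern(90, 2), particle_source(), cfg)
  rec <- res$records
  stick <- rec[rec$status == "stuck" & rec$lobe %in% c("left", "right"), ]
  m <- pi / 6 * (stick$d_um * 1e-6)^3 * stick$rho_p
  rf2 <- regional_fractions(res$tally)
  expect_equal(rf2$mdf_L, sum(m[stick$lobe == "left"]) / sum(m))
  expect_equal(rf2$ndf_L, mean(stick$lobe == "left"))
})

test_that("tally rebuilt from records equals the simulation tally", {
  tr <- simple_bifurcation()
  cfg <- simulation_config(n_particles = 500, seed = 17)
  res <- simulate_deposition(tr, breathing_pattern(90, 2), particle_source(), cfg)
  tl2 <- tally_from_records(res$records)
  expect_equal(unclass(tl2), unclass(res$tally))
})

test_that("impaction parameter and exclusion filter follow the convention", {
  expect_equal(impaction_parameter(10, 60), 6000)
  cur <- impaction_curve(d_um = c(0.03, 0.0316228, 1, 10),
                         efficiency = c(0.01, 0.02, 0.1, 0.9), Q = 100)
  # 0.03^2*100 = 0.09 excluded; 0.1 retained
  expect_equal(nrow(cur), 3)
  expect_equal(min(cur$impaction_parameter), 0.1, tolerance = 1e-4)
  expect_true(!is.unsorted(cur$impaction_parameter))
  # a waveform contributes its mean inspiratory flow
  cur2 <- impaction_curve(10, 0.5, breathing_pattern(90, 2))
  expect_equal(cur2$impaction_parameter, 100 * 2 / pi * 90, tolerance = 1e-9)
})

test_that("size histograms are normalized densities on 19 bins", {
  cfgm <- metrics_config(icrp_correction = 0)
  h <- size_histogram(rep(2.5, 100), cfgm)
  expect_equal(nrow(h), 19)
  expect_equal(sum(h$count > 0), 1)
  expect_equal(sum(h$density * (h$bin_hi - h$bin_lo)), 1)
  expect_error(size_histogram(numeric(0), cfgm), "empty")
  # samples from the truncated source log-normal recover the analytic pdf
  src <- particle_source("lognormal", range_um = c(0, 10))
  d <- sample_particle_sizes(4e4, src, seed = 8)
  h2 <- size_histogram(d, cfgm)
  pdf_ln <- function(x) stats::dlnorm(x, log(0.42), log(3.5)) /
    stats::plnorm(10, log(0.42), log(3.5))
  expected <- vapply(seq_len(19), function(i)
    stats::integrate(pdf_ln, h2$bin_lo[i], h2$bin_hi[i])$value, numeric(1)) /
    (h2$bin_hi - h2$bin_lo)
  # binomial sampling error: compare where the expected density is material
  big <- expected > 0.005
  expect_equal(h2$density[big], expected[big], tolerance = 0.1)
  # concatenation of two runs equals the count-weighted merge
  d2 <- sample_particle_sizes(2e4, src, seed = 9)
  hc <- size_histogram(c(d, d2), cfgm)
  h3 <- size_histogram(d2, cfgm)
  merged <- (h2$count + h3$count) / sum(h2$count + h3$count) /
    (hc$bin_hi - hc$bin_lo)
  expect_equal(hc$density, merged, tolerance = 1e-12)
})

test_that("the packaged deposition summary table is internally consistent", {
  tab <- read_deposition_table()
  expect_identical(nrow(tab), 8L)
  expect_true(all(abs(tab$mdf_L + tab$mdf_R - 100) <= 0.6))
  expect_true(all(abs(tab$ndf_L + tab$ndf_R - 100) <= 0.6))
  # a corrupted row is caught
  f <- withr::local_tempfile(fileext = ".csv")
  bad <- tab
  bad$mdf_L[1] <- bad$mdf_L[1] + 5
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(read_deposition_table(f), "sum to 100")
})
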