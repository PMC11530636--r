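air_293 <- air_properties(temperature_K = 293, viscosity_Pas = 1.81e-5)

test_that("log-normal source sampling recovers its parameters", {
  src <- particle_source("lognormal", cmd_um = 0.42, gsd = 3.5)
  d <- sample_particle_sizes(2e5, src, seed = 10)
  expect_equal(exp(mean(log(d))), 0.42, tolerance = 0.01)
  expect_equal(exp(sd(log(d))), 3.5, tolerance = 0.01)
  # determinism and truncation
  expect_identical(d[1:10], sample_particle_sizes(10, src, seed = 10))
  src_tr <- particle_source("lognormal", range_um = c(0.1, 10))
  dt <- sample_particle_sizes(1e4, src_tr, seed = 2)
  expect_true(all(dt >= 0.1 & dt <= 10))
  # degenerate limit gsd -> 1+
  src1 <- particle_source("lognormal", cmd_um = 1, gsd = 1 + 1e-9)
  expect_equal(sample_particle_sizes(100, src1, seed = 1), rep(1, 100),
               tolerance = 1e-6)
  expect_error(particle_source("lognormal", gsd = 1), "gsd")
})

test_that("drag coefficient follows Schiller-Naumann with Newton plateau", {
  expect_equal(drag_coefficient(1), 27.6, tolerance = 1e-12)
  expect_equal(drag_coefficient(2000), 0.44)
  # Stokes limit: C_d * Re -> 24
  re <- 10^seq(-6, -3)
  expect_equal(drag_coefficient(re) * re, rep(24, length(re)), tolerance = 1e-3)
  expect_equal(drag_factor(0), 1)
  expect_error(drag_coefficient(-1), "Re_p")
})

test_that("force-free particles move ballistically", {
  pos <- matrix(c(0, 0, 0), 1, 3)
  vel <- matrix(c(1, -2, 0.5), 1, 3)
  st <- advance_particles(pos, vel, 1e-6, matrix(0, 1, 3), dt = 0.1,
                          rho_p = 1000, forces = character(0))
  expect_equal(st$pos, vel * 0.1)
  expect_equal(st$vel, vel)
})

test_that("settling reaches the Stokes terminal velocity", {
  d <- 1e-5
  pos <- matrix(0, 1, 3); vel <- matrix(0, 1, 3)
  for (i in 1:100)  {
    st <- advance_particles(pos, vel, d, matrix(0, 1, 3), dt = 2e-4,
                            rho_p = 1000, air = air_293,
                            forces = c("drag", "gravity"))
    pos <- st$pos; vel <- st$vel
  }
  v_t <- stokes_terminal_velocity(d, 1000, air_293)
  expect_equal(v_t, 3.01e-3, tolerance = 0.01)
  expect_equal(-vel[1, 3], v_t, tolerance = 0.01)
})

test_that("velocity relaxes to the flow with time constant tau_p", {
  d <- 1e-5; rho <- 1000
  tau <- particle_relaxation_time(d, rho, air_293)
  u <- matrix(c(1e-4, 0, 0), 1, 3)   # slip small enough to stay in Stokes drag
  pos <- matrix(0, 1, 3); vel <- matrix(0, 1, 3)
  nst <- 8
  for (i in 1:nst) {
    st <- advance_particles(pos, vel, d, u, dt = tau / 2, rho_p = rho,
                            air = air_293, forces = "drag")
    pos <- st$pos; vel <- st$vel
  }
  expect_equal(vel[1, 1], u[1] * (1 - exp(-nst / 2)), tolerance = 1e-3)
})

test_that("Brownian motion reproduces the Einstein relation", {
  d <- 1e-6
  D <- particle_diffusivity(d, air_293)
  expect_equal(D, 2.37e-11, tolerance = 0.005)   # 1 um at 293 K
  # zero-temperature limit
  cold <- air_properties(temperature_K = 0, viscosity_Pas = 1.81e-5)
  expect_equal(brownian_kick(d, cold, 1e-3, n = 5), matrix(0, 5, 3))
  # free diffusion MSD = 2 D t per axis
  set.seed(99)
  n <- 1e4
  pos <- matrix(0, n, 3); vel <- matrix(0, n, 3)
  dm <- rep(d, n); u0 <- matrix(0, n, 3)
  dt <- 1e-3; nstep <- 150
  for (i in seq_len(nstep)) {
    st <- advance_particles(pos, vel, dm, u0, dt = dt, rho_p = 1000,
                            air = air_293, forces = c("drag", "brownian"))
    pos <- st$pos; vel <- st$vel
  }
  msd <- colMeans(pos^2)
  expect_equal(unname(msd), rep(2 * D * dt * nstep, 3), tolerance = 0.05)
})

test_that("every injected particle ends in exactly one fate and mass is conserved", {
  tr <- generate_airway_tree(tree_spec(16.2, 79.1, n_generations = 5, seed = 4))
  cfg <- simulation_config(n_particles = 1500, dt_flow = 0.02, seed = 21,
                           snapshot_times = c(3, 4))
  res <- simulate_deposition(tr, breathing_pattern(90, 2),
                             particle_source(), cfg)
  tl <- res$tally
  expect_identical(tl$n_stick + tl$n_scape + tl$n_exhaled + tl$n_airborne,
                   tl$n_total)
  expect_identical(tl$n_total, 1500L)
  m_rec <- sum(pi / 6 * (res$records$d_um * 1e-6)^3 * res$records$rho_p)
  expect_equal(tl$m_total, m_rec, tolerance = 1e-12)
  expect_equal(tl$m_stick + tl$m_scape + tl$m_exhaled + tl$m_airborne,
               tl$m_total, tolerance = 1e-12)
  # lobe splits only cover lobe-resolved sticks
  expect_lte(tl$n_stick_L + tl$n_stick_R, tl$n_stick)
})

test_that("fixed seed gives bit-identical tallies", {
  tr <- simple_bifurcation()
  cfg <- simulation_config(n_particles = 400, seed = 33)
  br <- breathing_pattern(90, 2)
  r1 <- simulate_deposition(tr, br, particle_source(), cfg)
  r2 <- simulate_deposition(tr, br, particle_source(), cfg)
  expect_identical(r1$records, r2$records)
})

test_that("diffusion deposition in a tube matches Gormley-Kennedy", {
  tube <- straight_tube(diameter = 1, length = 50)
  air <- air_properties()
  d_um <- 0.1
  D <- particle_diffusivity(d_um * 1e-6, air)
  L <- 0.05
  for (xi in c(0.01, 0.05)) {
    Q <- pi * D * L / xi
    u_mean <- Q / (pi * (5e-4)^2)
    cfg <- simulation_config(n_particles = 2500, rho_p = 1000, dt_flow = 1,
                             t_total = 8 * L / u_mean,
                             injection_window = c(0, 0),
                             forces = c("drag", "brownian"),
                             gravity = c(0, 0, 0), seed = 11)
    res <- simulate_deposition(tube, steady_breathing(Q * 60000),
                               particle_source("uniform", size_um = d_um), cfg)
    tl <- res$tally
    eff <- tl$n_stick / (tl$n_stick + tl$n_scape)
    expect_equal(eff, gormley_kennedy_efficiency(xi), tolerance = 0.1)
  }
})

test_that("gravitational deposition matches the laminar sedimentation formula", {
  tube <- straight_tube(diameter = 2, length = 100)   # horizontal
  air <- air_properties()
  R <- 1e-3; L <- 0.1; U <- 0.2
  Q <- U * pi * R^2
  for (dm in c(5, 10)) {
    cfg <- simulation_config(n_particles = 3000, rho_p = 1000, dt_flow = 1,
                             t_total = 6 * L / U, injection_window = c(0, 0),
                             forces = c("drag", "gravity"),
                             gravity = c(0, 0, -9.81), seed = 3)
    res <- simulate_deposition(tube, steady_breathing(Q * 60000),
                               particle_source("uniform", size_um = dm), cfg)
    tl <- res$tally
    eff <- tl$n_stick / (tl$n_stick + tl$n_scape)
    vs <- stokes_terminal_velocity(dm * 1e-6, 1000, air)
    expect_equal(eff, pich_sedimentation_efficiency(vs, L, R, U),
                 tolerance = 0.1)
  }
})

test_that("impaction capture grows with the impaction parameter on a bend", {
  # two perpendicular segments: classic impaction geometry
  seg <- data.frame(
    id = 1:2, parent_id = c(NA, 1L), generation = 0:1,
    px = c(0, 40), py = 0, pz = 0, dx = c(40, 40), dy = 0, dz = c(0, -40),
    diameter = 4, lobe = "central")
  bend <- airway_tree(seg)
  effs <- vapply(c(5, 8, 12, 16), function(dm) {
    cfg <- simulation_config(n_particles = 1200, rho_p = 1000, dt_flow = 0.5,
                             t_total = 2, injection_window = c(0, 0),
                             forces = c("drag", "gravity"), seed = 5)
    res <- simulate_deposition(bend, steady_breathing(30),
                               particle_source("uniform", size_um = dm), cfg)
    res$tally$n_stick / res$tally$n_total
  }, numeric(1))
  expect_true(all(diff(effs) >= 0))
})

test_that("halving the sub-step changes the deposition fraction by under 1%", {
  # drag + gravity only: trajectories are deterministic given the injected
  # sizes, so the difference between runs is pure time-discretization error
  tr <- simple_bifurcation()
  br <- breathing_pattern(90, 2)
  run <- function(frac) {
    cfg <- simulation_config(n_particles = 1200, seed = 14,
                             substep_transit_frac = frac,
                             forces = c("drag", "gravity"),
                             injection_window = c(2, 3))
    res <- simulate_deposition(tr, br, particle_source(), cfg)
    cfgm <- metrics_config(icrp_correction = 0)
    ndf(res$tally, cfgm)
  }
  base <- run(1 / 20)
  expect_lt(abs(run(1 / 40) - base), 0.01)
})

test_that("track records round-trip through CSV", {
  tr <- simple_bifurcation()
  cfg <- simulation_config(n_particles = 200, seed = 3)
  res <- simulate_deposition(tr, breathing_pattern(90, 2), particle_source(), cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks(res$records, f)
  rec <- read_tracks(f)
  expect_equal(rec$status, res$records$status)
  expect_equal(rec$x, res$records$x, tolerance = 1e-12)
  expect_error(read_tracks({
    f2 <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), f2, row.names = FALSE)
    f2
  }), "missing column")
})
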