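quick_cfg <- function(...) {
  simulation_config(
    porous = porous_params(area_expansion = 1e6),
    solver = solver_config(newtonian_override = 2.2e-3),
    nz = 50, nr = 10, wall_cluster = 0, ...)
}

test_that("rigid mode does one fluid solve and never touches wall or mesh", {
  cfg <- quick_cfg(wall = wall_params(rigid = TRUE))
  mesh <- build_mesh(cfg$geometry, cfg$nz, cfg$nr, 0)
  fl <- fluid_state(mesh); wl <- wall_state(mesh$nz_art)
  stp <- step_coupled(fl, wl, mesh, 0.3, cfg)
  expect_identical(stp$subiterations, 1L)
  expect_identical(stp$mesh$Rw_c, mesh$Rw_c)
  expect_identical(stp$wall$d, numeric(mesh$nz_art))
  expect_identical(stp$interface_residual, 0)
})

test_that("zero inflow from rest converges in one sub-iteration at zero residual", {
  cfg <- quick_cfg()
  mesh <- build_mesh(cfg$geometry, cfg$nz, cfg$nr, 0)
  stp <- step_coupled(fluid_state(mesh), wall_state(mesh$nz_art),
                      mesh, 0, cfg)
  expect_identical(stp$subiterations, 1L)
  expect_identical(stp$interface_residual, 0)
  expect_identical(max(abs(stp$fluid$vz)), 0)
})

test_that("steady coupled inflation matches the static ring closed form", {
  cfg <- quick_cfg(wall = wall_params(damping = 3e4))
  cfg$nz <- 60; cfg$nr <- 16
  mesh <- build_mesh(cfg$geometry, cfg$nz, cfg$nr, 0)
  fl <- fluid_state(mesh); wl <- wall_state(mesh$nz_art)
  for (n in 1:120) {
    stp <- step_coupled(fl, wl, mesh, 0.2, cfg)
    fl <- stp$fluid; wl <- stp$wall; mesh <- stp$mesh
  }
  trac <- wall_traction(fl, mesh, cfg$rheology)
  d_exp <- static_displacement(cfg$wall, trac)
  interior <- 10:30
  expect_equal(wl$d[interior], d_exp[interior], tolerance = 0.01)
  expect_lte(stp$interface_residual, cfg$coupling$interface_tol)
})

test_that("run length follows cycles * period / dt and records every step", {
  cfg <- quick_cfg(wall = wall_params(rigid = TRUE),
                   coupling = coupling_config(cycles = 1,
                                              analysis_cycle = 1))
  cfg$solver$dt <- 0.01
  run <- suppressWarnings(run_simulation(cfg))
  expect_equal(length(run$series$time), 80)
  expect_equal(length(run$analysis$time), 80)
  # defaults contract: 3 x 0.8 s / 4e-3 s
  d <- simulation_config()
  expect_equal(d$coupling$cycles * round(d$waveform$period / d$solver$dt),
               600)
})

test_that("identical configurations give bit-identical results", {
  cfg <- quick_cfg(coupling = coupling_config(cycles = 1,
                                              analysis_cycle = 1))
  cfg$solver$dt <- 8e-3
  r1 <- suppressWarnings(run_simulation(cfg))
  r2 <- suppressWarnings(run_simulation(cfg))
  expect_identical(r1$series$sections, r2$series$sections)
  expect_identical(r1$wall_d, r2$wall_d)
})

test_that("rigid and compliant runs share the identical inlet series", {
  cfg <- quick_cfg(coupling = coupling_config(cycles = 1,
                                              analysis_cycle = 1))
  cfg$solver$dt <- 8e-3
  rc <- suppressWarnings(run_simulation(cfg))
  cfg$wall$rigid <- TRUE
  rr <- suppressWarnings(run_simulation(cfg))
  expect_identical(rc$inlet_flux, rr$inlet_flux)
})

test_that("single-element stiffness sweep reproduces the baseline run", {
  cfg <- quick_cfg(coupling = coupling_config(cycles = 1,
                                              analysis_cycle = 1))
  cfg$solver$dt <- 8e-3
  base <- suppressWarnings(run_simulation(cfg))
  tab <- suppressWarnings(sensitivity_sweep(5e6, cfg))
  expect_equal(tab$peak_wss_S1,
               base$summary$peak_wss[base$summary$section == "S1"])
  expect_error(sensitivity_sweep(c(5e6, -1), cfg), "positive")
})

test_that("IQN-ILS needs no more sub-iterations than Aitken, Aitken no more than fixed", {
  counts <- sapply(c("iqn_ils", "aitken", "fixed"), function(rel) {
    cfg <- quick_cfg(coupling = coupling_config(relaxation = rel,
                                                cycles = 1,
                                                analysis_cycle = 1))
    cfg$solver$dt <- 8e-3
    cfg$nz <- 40; cfg$nr <- 10
    mesh <- build_mesh(cfg$geometry, cfg$nz, cfg$nr, 0)
    fl <- fluid_state(mesh); wl <- wall_state(mesh$nz_art)
    tot <- 0
    for (n in 1:25) {
      stp <- step_coupled(fl, wl, mesh, 0.1 + 0.05 * sin(n / 5), cfg)
      fl <- stp$fluid; wl <- stp$wall; mesh <- stp$mesh
      tot <- tot + stp$subiterations
    }
    tot
  })
  expect_lte(counts[["aitken"]], counts[["fixed"]])
  expect_lte(counts[["iqn_ils"]], counts[["aitken"]])
})

test_that("pulse transit speed between S1 and S2 matches Moens-Korteweg within 15%", {
  geo <- geometry_config(artery_length = 0.5, micro_length = 0.05)
  cfg <- simulation_config(
    geometry = geo,
    porous = porous_params(area_expansion = 1e6),
    # light damping and high-frequency dissipation stabilise the very
    # small coupling time step; neither changes the propagation speed
    wall = wall_params(damping = 2e4, newmark_gamma = 0.6),
    solver = solver_config(dt = 2e-4, newtonian_override = 2.2e-3),
    coupling = coupling_config(max_subiterations = 100),
    nz = 150, nr = 12, wall_cluster = 0)
  mesh <- build_mesh(geo, cfg$nz, cfg$nr, 0)
  fl <- fluid_state(mesh); wl <- wall_state(mesh$nz_art)
  pulse <- function(t) 0.05 * exp(-((t - 0.008) / 2e-3)^2)
  n_steps <- 150
  p1 <- numeric(n_steps); p2 <- numeric(n_steps)
  i1 <- mesh$probes[["S1"]]; i2 <- mesh$probes[["S2"]]
  for (n in 1:n_steps) {
    stp <- step_coupled(fl, wl, mesh, pulse(n * cfg$solver$dt), cfg)
    fl <- stp$fluid; wl <- stp$wall; mesh <- stp$mesh
    p1[n] <- mean(fl$p[i1, ]); p2[n] <- mean(fl$p[i2, ])
  }
  # lag of the cross-correlation maximum, parabolically refined
  lags <- 5:60
  cc <- sapply(lags, function(k)
    sum(p1[1:(n_steps - k)] * p2[(k + 1):n_steps]))
  kbest <- which.max(cc)
  k0 <- lags[kbest]
  if (kbest > 1 && kbest < length(lags)) {
    a <- cc[kbest - 1]; b <- cc[kbest]; d <- cc[kbest + 1]
    k0 <- k0 + 0.5 * (a - d) / (a - 2 * b + d)
  }
  c_meas <- (mesh$zc[i2] - mesh$zc[i1]) / (k0 * cfg$solver$dt)
  c_mk <- moens_korteweg_speed(5e6, 0.002, 1050, 0.01)
  expect_equal(c_meas, c_mk, tolerance = 0.15)
})

test_that("successive cycles approach a periodic steady state", {
  run <- get_baseline_run()
  T0 <- run$config$waveform$period
  s2 <- cycle_summary(extract_cycle(run$series, 2, T0))
  s3 <- run$summary
  expect_equal(s2$peak_pressure, s3$peak_pressure, tolerance = 0.02)
  # centreline velocities still carry the slow near-wall viscous
  # development transient (time scale rho R^2 / eta >> 3 T); peaks track
  # to a few percent
  expect_equal(s2$peak_velocity, s3$peak_velocity, tolerance = 0.08)
})
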