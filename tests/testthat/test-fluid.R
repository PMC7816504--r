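# steady/transient verification of the fluid solver on small grids; the
# acceptance-grade resolutions live in test-acceptance.R

test_that("zero inlet keeps the rest state exactly at rest", {
  mesh <- build_mesh(geometry_config(micro_length = 0), nz = 30, nr = 8)
  st <- advance_fluid(fluid_state(mesh), mesh, 0,
                      config = solver_config(dt = 0.01))
  expect_identical(max(abs(st$vz)), 0)
  expect_identical(max(abs(st$p)), 0)
  expect_equal(st$div_residual, 0)
})

test_that("steady Poiseuille flow reproduces the 4 eta U / R wall shear", {
  mesh <- build_mesh(geometry_config(micro_length = 0), nz = 40, nr = 16,
                     wall_cluster = 0)
  cfg <- solver_config(dt = 0.05, newtonian_override = 2.2e-3)
  st <- fluid_state(mesh)
  for (i in 1:60) st <- advance_fluid(st, mesh, 0.1, config = cfg)
  wss <- wall_shear_stress(st, mesh, eta_override = 2.2e-3)
  expect_equal(wss[20], 4 * 2.2e-3 * 0.1 / 0.01, tolerance = 0.01)
  # centreline velocity of the parabolic profile is 2 * u_mean
  vzc <- 0.5 * (st$vz[20, ] + st$vz[21, ])
  expect_equal(vzc[1], 0.2, tolerance = 0.01)
})

test_that("steady seepage column obeys Darcy's law", {
  por <- porous_params(viscosity_mode = "eta_inf")
  L <- 0.05
  mesh <- build_mesh(geometry_config(artery_length = 0, micro_length = L),
                     nz = 20, nr = 8, wall_cluster = 0)
  cfg <- solver_config(dt = 0.05, newtonian_override = 2.2e-3,
                       inlet_profile = "plug")
  st <- fluid_state(mesh)
  q <- 1e-9
  for (i in 1:40) st <- advance_fluid(st, mesh, q, porous = por, config = cfg)
  # pressure at the first cell centre vs the analytic drop over that span
  L_eff <- L - mesh$dz[1] / 2
  dp_exact <- 2.2e-3 * q * L_eff / por$permeability
  expect_equal(mean(st$p[1, ]), dp_exact, tolerance = 0.01)
  expect_equal(dp_exact * L / L_eff, 0.619, tolerance = 0.03)
})

test_that("wall traction reduces to pressure for hydrostatic and Poiseuille states", {
  mesh <- build_mesh(geometry_config(micro_length = 0), nz = 40, nr = 16,
                     wall_cluster = 0)
  st <- fluid_state(mesh)
  st$p[] <- 123.4                       # hydrostatic rest state
  expect_equal(wall_traction(st, mesh), rep(123.4, mesh$nz_art))
  cfg <- solver_config(dt = 0.05, newtonian_override = 2.2e-3)
  st <- fluid_state(mesh)
  for (i in 1:60) st <- advance_fluid(st, mesh, 0.1, config = cfg)
  gp_wgt <- rowMeans(st$p)              # p nearly uniform radially
  trac <- wall_traction(st, mesh)
  expect_equal(trac, gp_wgt[seq_along(trac)], tolerance = 0.01)
})

test_that("wall traction balances the axial pressure force budget at steady state", {
  mesh <- build_mesh(geometry_config(micro_length = 0), nz = 40, nr = 16,
                     wall_cluster = 0)
  cfg <- solver_config(dt = 0.05, newtonian_override = 2.2e-3)
  st <- fluid_state(mesh)
  for (i in 1:80) st <- advance_fluid(st, mesh, 0.1, config = cfg)
  trac <- wall_traction(st, mesh)
  p_in <- mean(st$p[1, ]) + (mean(st$p[1, ]) - mean(st$p[2, ])) / 2
  # developed flow: traction decays linearly inlet -> outlet like p
  expect_equal(mean(trac), p_in / 2, tolerance = 0.04)
})

test_that("interface diagnostics vanish at rest and stay tiny in steady flow", {
  cfg <- simulation_config(
    porous = porous_params(area_expansion = 1e6),
    wall = wall_params(rigid = TRUE),
    solver = solver_config(dt = 0.02, newtonian_override = 2.2e-3),
    nz = 60, nr = 12, wall_cluster = 0)
  mesh <- build_mesh(cfg$geometry, cfg$nz, cfg$nr, 0)
  st0 <- fluid_state(mesh)
  z0 <- zone_interface_fluxes(st0, mesh, cfg$porous)
  expect_identical(z0$flux_mismatch, 0)
  expect_identical(z0$pressure_jump, 0)
  st <- st0
  for (i in 1:80)
    st <- advance_fluid(st, mesh, 0.1, porous = cfg$porous,
                        config = cfg$solver)
  zi <- zone_interface_fluxes(st, mesh, cfg$porous)
  expect_lt(zi$flux_mismatch, 1e-3)
  expect_lt(zi$pressure_jump_rel, 0.05)
  expect_equal(zi$flux_artery, zi$flux_porous, tolerance = 1e-3)
})

test_that("porous operators reduce to artery operators as phi -> 1, sink -> 0", {
  # same axial spacing in both partitions: 0.2 + 0.1 over 30 columns
  g2 <- geometry_config()                       # two zones
  g1 <- geometry_config(artery_length = 0.3, micro_length = 0)
  m2 <- build_mesh(g2, nz = 30, nr = 8, wall_cluster = 0)
  m1 <- build_mesh(g1, nz = 30, nr = 8, wall_cluster = 0)
  expect_equal(m1$zf, m2$zf)
  st <- fluid_state(m2)
  cfg <- solver_config(dt = 4e-3, newtonian_override = 2.2e-3)
  por_neutral <- porous_params(porosity = 1 - 1e-12, permeability = 1e6)
  ctx2 <- hemofsi:::fluid_step_context(st, m2, rheology_params(),
                                       por_neutral, cfg, rep(0.1, 8), 4e-3)
  ctx1 <- hemofsi:::fluid_step_context(st, m1, rheology_params(),
                                       porous_params(), cfg, rep(0.1, 8),
                                       4e-3)
  expect_lt(max(abs(ctx2$M - ctx1$M)) / max(abs(ctx1$M)), 1e-9)
})

test_that("advection-scheme order barely changes cycle-integrated inlet mass", {
  base <- simulation_config(
    porous = porous_params(area_expansion = 1e6),
    wall = wall_params(rigid = TRUE),
    coupling = coupling_config(cycles = 1, analysis_cycle = 1),
    nz = 50, nr = 10, wall_cluster = 0)
  base$solver$dt <- 8e-3
  hi <- suppressWarnings(run_simulation(base))
  base$solver$advection <- "upwind"
  lo <- suppressWarnings(run_simulation(base))
  vol_hi <- sum(hi$outlet_flux) * base$solver$dt
  vol_lo <- sum(lo$outlet_flux) * base$solver$dt
  expect_equal(vol_hi, vol_lo, tolerance = 0.01)
})
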