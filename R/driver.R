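#' Partitioned coupling configuration
#'
#' Settings of the staggered fluid-wall coupling: per time step the
#' fluid is solved with the current interface velocity, the wall is
#' advanced under the resulting traction, and the interface displacement
#' is relaxed (dynamic Aitken by default) until its relative change
#' drops below `interface_tol`.
#'
#' @param interface_tol Relative interface-displacement tolerance.
#' @param max_subiterations Sub-iteration cap per step.
#' @param relaxation Interface update: `"iqn_ils"` (interface
#'   quasi-Newton from the sub-iteration residual history, the default —
#'   the strong added-mass coupling of a nearly incompressible fluid in
#'   a light wall makes scalar relaxation slow), `"aitken"` (dynamic
#'   scalar) or `"fixed"`.
#' @param omega Initial / fixed relaxation factor.
#' @param cycles Number of cardiac cycles to integrate.
#' @param analysis_cycle Cycle extracted for analysis (1-based).
#' @return An object of class `coupling_config`.
#' @export
coupling_config <- function(interface_tol = 1e-4, max_subiterations = 50,
                            relaxation = c("iqn_ils", "aitken", "fixed"),
                            omega = 0.5, cycles = 3, analysis_cycle = 3) {
  relaxation <- match.arg(relaxation)
  if (interface_tol <= 0) stop("interface_tol must be > 0", call. = FALSE)
  if (cycles < analysis_cycle || analysis_cycle < 1)
    stop("need cycles >= analysis_cycle >= 1", call. = FALSE)
  structure(list(interface_tol = interface_tol,
                 max_subiterations = max_subiterations,
                 relaxation = relaxation, omega = omega,
                 cycles = cycles, analysis_cycle = analysis_cycle),
            class = "coupling_config")
}

#' Bundle all simulation settings
#'
#' Aggregates the per-module configuration objects and the mesh
#' resolution into one run description with the study defaults.
#'
#' @param geometry [geometry_config()].
#' @param rheology [rheology_params()].
#' @param porous [porous_params()].
#' @param wall [wall_params()] (its `reference_radius` is synchronised
#'   with the geometry).
#' @param waveform [waveform_config()].
#' @param solver [solver_config()].
#' @param coupling [coupling_config()].
#' @param nz,nr,wall_cluster Mesh resolution passed to [build_mesh()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = geometry_config(),
                              rheology = rheology_params(),
                              porous = porous_params(),
                              wall = wall_params(),
                              waveform = waveform_config(),
                              solver = solver_config(),
                              coupling = coupling_config(),
                              nz = 150, nr = 24, wall_cluster = 1.5) {
  wall$reference_radius <- geometry$radius
  structure(list(geometry = geometry, rheology = rheology, porous = porous,
                 wall = wall, waveform = waveform, solver = solver,
                 coupling = coupling, nz = nz, nr = nr,
                 wall_cluster = wall_cluster),
            class = "simulation_config")
}

# Newmark-consistent interface velocity for a trial end-of-step
# displacement
newmark_velocity <- function(d_trial, wall, dt, params) {
  gamma <- params$newmark_gamma
  beta <- (gamma + 0.5)^2 / 4
  dp <- wall$d + dt * wall$v + dt^2 * (0.5 - beta) * wall$a
  vp <- wall$v + dt * (1 - gamma) * wall$a
  vp + gamma / (beta * dt) * (d_trial - dp)
}

#' One coupled fluid-wall-mesh time step
#'
#' Sub-iterates fluid solve, traction transfer, wall advance and
#' relaxation until the interface displacement settles; then deforms the
#' mesh to the accepted displacement.  The mesh geometry and fluid
#' operators are frozen at the Newmark-predicted displacement for the
#' step (the difference to the accepted displacement is of the size of
#' the interface tolerance), while the interface no-slip velocity always
#' uses the current iterate, so the kinematic condition holds at
#' convergence.  In rigid mode a single fluid solve is performed and
#' wall and mesh are untouched.
#'
#' @param fluid [fluid_state()] at t(n).
#' @param wall [wall_state()] at t(n).
#' @param mesh Mesh at t(n).
#' @param inlet_velocity Mean inlet velocity at t(n+1) (m/s).
#' @param config A [simulation_config()].
#' @return List with `fluid`, `wall`, `mesh`, `subiterations`,
#'   `interface_residual`.
#' @export
step_coupled <- function(fluid, wall, mesh, inlet_velocity, config) {
  dt <- config$solver$dt
  t_new <- fluid$time + dt
  inlet_vec <- inlet_profile_vec(inlet_velocity, mesh, config$solver, t_new)
  if (config$wall$rigid || mesh$nz_art == 0) {
    ctx <- fluid_step_context(fluid, mesh, config$rheology, config$porous,
                              config$solver, inlet_vec, t_new)
    fl <- fluid_solve_step(ctx, rep(0, mesh$nz))
    wl <- if (mesh$nz_art > 0) {
      w <- wall; w$time <- t_new; w
    } else wall
    return(list(fluid = fl, wall = wl, mesh = mesh,
                subiterations = 1L, interface_residual = 0))
  }
  cc <- config$coupling
  d_n <- wall$d
  # Newmark predictor for the frozen step geometry
  d_star <- wall$d + dt * wall$v + 0.5 * dt^2 * wall$a
  mesh_star <- deform_mesh(mesh, d_star, dt, previous_displacement = d_n)
  # the interface iteration needs a quieter fluid map than its own
  # tolerance, otherwise the traction noise floor blocks convergence
  solver_sharp <- config$solver
  solver_sharp$residual_tol <- 0.2 * config$solver$residual_tol
  ctx <- fluid_step_context(fluid, mesh_star, config$rheology,
                            config$porous, solver_sharp, inlet_vec, t_new)
  nz <- mesh$nz
  d_k <- d_star
  omega <- cc$omega
  r_prev <- NULL
  D_hist <- NULL; G_hist <- NULL
  wall_new <- NULL; fl <- NULL; warm <- NULL
  for (k in seq_len(cc$max_subiterations)) {
    wall_vr <- c(newmark_velocity(d_k, wall, dt, config$wall),
                 rep(0, nz - mesh$nz_art))
    fl <- fluid_solve_step(ctx, wall_vr, warm = warm)
    warm <- fl
    trac <- wall_traction(fl, mesh_star, config$rheology)
    wall_new <- advance_wall_impl(wall, trac, config$wall, dt)
    r_k <- wall_new$d - d_k
    # relative interface tolerance with an absolute floor far below any
    # physically meaningful displacement (1e-8 of the radius, ~0.1 nm)
    if (max(abs(r_k)) <= max(cc$interface_tol * max(abs(wall_new$d)),
                             1e-8 * config$wall$reference_radius)) {
      d_k <- wall_new$d
      break
    }
    if (k == cc$max_subiterations)
      stop(sprintf(
        "FSI sub-iterations did not converge (residual %.3g rel)",
        max(abs(r_k)) / max(max(abs(wall_new$d)), 1e-14)),
        call. = FALSE)
    d_prev_it <- d_k
    if (cc$relaxation == "iqn_ils") {
      D_hist <- cbind(D_hist, d_k); G_hist <- cbind(G_hist, wall_new$d)
      if (ncol(D_hist) > 12) {               # window the secant history
        D_hist <- D_hist[, -1, drop = FALSE]
        G_hist <- G_hist[, -1, drop = FALSE]
      }
      nc <- ncol(D_hist)
      stepped <- FALSE
      if (nc >= 2) {
        Fh <- G_hist - D_hist
        dF <- Fh[, 2:nc, drop = FALSE] - Fh[, 1:(nc - 1), drop = FALSE]
        gam <- tryCatch(qr.coef(qr(dF, LAPACK = TRUE), r_k),
                        error = function(e) NULL)
        if (!is.null(gam) && all(is.finite(gam))) {
          dG <- G_hist[, 2:nc, drop = FALSE] -
            G_hist[, 1:(nc - 1), drop = FALSE]
          d_k <- wall_new$d - as.vector(dG %*% gam)
          stepped <- TRUE
        }
      }
      if (!stepped) d_k <- d_k + omega * r_k
    } else {
      if (cc$relaxation == "aitken" && !is.null(r_prev)) {
        dr <- r_k - r_prev
        denom <- sum(dr^2)
        if (denom > 0) omega <- -omega * sum(r_prev * dr) / denom
        omega <- min(max(omega, 0.02), 2)
      }
      d_k <- d_k + omega * r_k
      r_prev <- r_k
    }
    # keep trial iterates physical: limit the interface increment both in
    # displacement (fraction of the radius) and in the implied interface
    # velocity 2*inc/dt (the added-mass gain grows like 1/dt^2 and raw
    # quasi-Newton steps can otherwise go wild at small time steps)
    inc <- d_k - d_prev_it
    cap <- min(0.05 * config$wall$reference_radius, 0.25 * dt)
    if (max(abs(inc)) > cap)
      d_k <- d_prev_it + inc * cap / max(abs(inc))
  }
  if (any(abs(d_k) >= 0.5 * config$wall$reference_radius))
    stop("wall displacement exceeded half the radius: FSI divergence",
         call. = FALSE)
  mesh_new <- deform_mesh(mesh, d_k, dt, previous_displacement = d_n)
  list(fluid = fl, wall = wall_new, mesh = mesh_new,
       subiterations = k,
       interface_residual = max(abs(wall_new$d - d_k)) /
         max(max(abs(wall_new$d)), 1e-12))
}

probe_record <- function(fl, mesh, config) {
  gp <- mesh_geom_pack(mesh)
  nz <- gp$nz; nr <- gp$nr
  vzc <- 0.5 * (fl$vz[-1, , drop = FALSE] + fl$vz[-(nz + 1), , drop = FALSE])
  drw <- gp$rf[, -1, drop = FALSE] - gp$rf[, -(nr + 1), drop = FALSE]
  wgt <- gp$rc * drw
  pm <- rowSums(fl$p * wgt) / rowSums(wgt)
  wss <- wall_shear_stress(fl, mesh, config$rheology,
                           eta_override = config$solver$newtonian_override)
  phiA <- config$porous$porosity * config$porous$area_expansion
  out <- lapply(names(mesh$probes), function(nm) {
    i <- mesh$probes[[nm]]
    vmax <- max(vzc[i, ])
    w <- wss[i]
    if (mesh$zone[i] == "micro") {     # intrinsic (bed-frame) quantities
      vmax <- vmax / phiA
      w <- w / phiA
    }
    c(pressure = pm[i], velocity = vmax, wss = w)
  })
  names(out) <- names(mesh$probes)
  out
}

#' Run a multi-cycle coupled simulation
#'
#' Integrates the coupled system from rest over the configured number of
#' cardiac cycles, recording per-step probe series at the S1-S4
#' sections, wall displacement, boundary fluxes and sub-iteration
#' counts.  The run is fully deterministic.
#'
#' @param config A [simulation_config()].
#' @param progress Print a line per cycle.
#' @return An object of class `hemo_run`: fields `series`
#'   ([probe_series()]), `analysis` (the extracted analysis cycle),
#'   `summary` ([cycle_summary()] of the analysis cycle), `wall_d`
#'   (stations x steps displacement matrix), `inlet_flux`/`outlet_flux`
#'   (m3/s), `subiterations`, `div_residual_max` and the config echo.
#' @export
run_simulation <- function(config = simulation_config(), progress = FALSE) {
  mesh <- build_mesh(config$geometry, nz = config$nz, nr = config$nr,
                     wall_cluster = config$wall_cluster)
  wf <- generate_waveform(config$waveform)
  dt <- config$solver$dt
  n_per <- round(config$waveform$period / dt)
  n_steps <- config$coupling$cycles * n_per
  fl <- fluid_state(mesh)
  wl <- wall_state(max(mesh$nz_art, 1L))
  probes <- names(mesh$probes)
  rec <- lapply(probes, function(nm)
    list(pressure = numeric(n_steps), velocity = numeric(n_steps),
         wss = numeric(n_steps)))
  names(rec) <- probes
  wall_d <- matrix(0, mesh$nz_art, n_steps)
  q_in <- numeric(n_steps); q_out <- numeric(n_steps)
  sub <- integer(n_steps); divmax <- 0; ifmax <- 0
  cfl_warned <- FALSE
  ramp <- config$solver$startup_ramp
  for (n in seq_len(n_steps)) {
    u_in <- sample_waveform(wf, n * dt)
    if (!is.null(ramp) && ramp > 0 && n * dt < ramp)
      u_in <- u_in * sin(pi * n * dt / (2 * ramp))^2
    stp <- step_coupled(fl, wl, mesh, u_in, config)
    fl <- stp$fluid; wl <- stp$wall; mesh <- stp$mesh
    sub[n] <- stp$subiterations
    divmax <- max(divmax, fl$div_residual)
    ifmax <- max(ifmax, stp$interface_residual)
    cfl <- max(abs(fl$vz)) * dt / min(mesh$dz)
    if (!cfl_warned && cfl > 1) {
      warning(sprintf(
        "advective CFL %.2f > 1 at t = %.3f s (implicit scheme: stable)",
        cfl, fl$time), call. = FALSE)
      cfl_warned <- TRUE
    }
    pr <- probe_record(fl, mesh, config)
    for (nm in probes) {
      rec[[nm]]$pressure[n] <- pr[[nm]]["pressure"]
      rec[[nm]]$velocity[n] <- pr[[nm]]["velocity"]
      rec[[nm]]$wss[n] <- pr[[nm]]["wss"]
    }
    if (mesh$nz_art > 0) wall_d[, n] <- c(wl$d, numeric(0))
    gp <- mesh_geom_pack(mesh)
    q_in[n] <- 2 * pi * sum(fl$vz[1, ] * gp$Az[1, ])
    q_out[n] <- 2 * pi * sum(fl$vz[mesh$nz + 1, ] * gp$Az[mesh$nz + 1, ])
    if (progress && n %% n_per == 0)
      message(sprintf("cycle %d/%d done (t = %.3f s)", n %/% n_per,
                      config$coupling$cycles, fl$time))
  }
  series <- probe_series(dt * seq_len(n_steps), rec)
  analysis <- extract_cycle(series, config$coupling$analysis_cycle,
                            config$waveform$period)
  structure(list(series = series, analysis = analysis,
                 summary = cycle_summary(analysis,
                                         config$coupling$analysis_cycle),
                 wall_d = wall_d, inlet_flux = q_in, outlet_flux = q_out,
                 subiterations = sub, div_residual_max = divmax,
                 interface_residual_max = ifmax,
                 final_fluid = fl, final_wall = wl, final_mesh = mesh,
                 config = config),
            class = "hemo_run")
}

#' @export
print.hemo_run <- function(x, ...) {
  cat(sprintf("<hemo_run> %d steps, %s wall, analysis cycle %d\n",
              length(x$series$time),
              if (x$config$wall$rigid) "rigid" else "compliant",
              x$config$coupling$analysis_cycle))
  print(x$summary)
  invisible(x)
}

#' Young's-modulus sensitivity sweep
#'
#' Repeats the baseline run for each stiffness value, all other
#' settings identical, and tabulates the analysis-cycle peak wall shear
#' stress (and peak pressure/velocity) at the artery sections.
#'
#' @param E_values Young's moduli (Pa), positive.
#' @param config Base [simulation_config()].
#' @param progress Passed to [run_simulation()].
#' @return A data frame with one row per stiffness.
#' @export
sensitivity_sweep <- function(E_values, config = simulation_config(),
                              progress = FALSE) {
  if (any(E_values <= 0)) stop("E_values must be positive", call. = FALSE)
  rows <- lapply(E_values, function(E) {
    cfg <- config
    cfg$wall$youngs_modulus <- E
    run <- tryCatch(run_simulation(cfg, progress = progress),
                    error = function(e)
                      stop(sprintf("sweep failed at E = %.3g Pa: %s",
                                   E, conditionMessage(e)), call. = FALSE))
    s <- run$summary
    data.frame(E = E,
               peak_wss_S1 = s$peak_wss[s$section == "S1"],
               peak_wss_S2 = s$peak_wss[s$section == "S2"],
               peak_velocity_S1 = s$peak_velocity[s$section == "S1"],
               peak_pressure_S1 = s$peak_pressure[s$section == "S1"])
  })
  do.call(rbind, rows)
}
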