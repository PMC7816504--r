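#' Fluid solver configuration
#'
#' Numerical settings of the incompressible axisymmetric ALE solver.
#' Time integration is second-order backward differencing (backward Euler
#' on the start-up step).  Pressure-velocity coupling is monolithic
#' (momentum and continuity solved as one sparse system per step);
#' convection and the shear-thinning viscosity are made implicit by an
#' inner defect-correction iteration that runs until the RMS-normalised
#' velocity residual drops below `residual_tol`.
#'
#' @param dt Time step (s).
#' @param residual_tol RMS-normalised residual tolerance of the inner
#'   defect-correction iterations.
#' @param max_inner_iterations Inner iteration cap before a convergence
#'   error is raised.
#' @param advection `"high_resolution"` (softened upwinding plus a
#'   smooth van Albada-limited second-order face correction) or
#'   `"upwind"` (softened first-order upwind only).
#' @param newtonian_override Fixed viscosity (Pa s) replacing the
#'   Carreau-Yasuda law, or `NULL`; used by the analytic verification
#'   oracles.
#' @param inlet_profile Radial shape of the imposed inlet axial velocity:
#'   `"parabolic"` (`2 u (1 - (r/R)^2)`, the default), `"plug"`, or a
#'   `function(xi, t)` returning the full profile on the normalized radii
#'   `xi` (the waveform mean is then ignored).
#' @param body_force Optional `function(t)` returning a uniform axial
#'   driving force density (Pa/m); used to set up fully developed
#'   oscillatory verification flows.
#' @param startup_ramp Smooth-start window (s) applied by
#'   [run_simulation()]: the inlet waveform is multiplied by
#'   `sin^2(pi t / (2 startup_ramp))` for `t < startup_ramp`, so the
#'   simulation starts from rest without an impulsive load on the wall.
#'   Only the (discarded) first cycle is affected.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dt = 4e-3, residual_tol = 1e-4,
                          max_inner_iterations = 60,
                          advection = c("high_resolution", "upwind"),
                          newtonian_override = NULL,
                          inlet_profile = "parabolic",
                          body_force = NULL, startup_ramp = 0.08) {
  advection <- match.arg(advection)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (residual_tol <= 0) stop("residual_tol must be > 0", call. = FALSE)
  if (!is.function(inlet_profile) &&
      !inlet_profile %in% c("parabolic", "plug"))
    stop("inlet_profile must be 'parabolic', 'plug' or a function",
         call. = FALSE)
  structure(list(dt = dt, residual_tol = residual_tol,
                 max_inner_iterations = max_inner_iterations,
                 advection = advection,
                 newtonian_override = newtonian_override,
                 inlet_profile = inlet_profile, body_force = body_force,
                 startup_ramp = startup_ramp),
            class = "solver_config")
}

#' Initialise a fluid state at rest
#'
#' @param mesh A [build_mesh()] result.
#' @param time Initial time (s).
#' @return An object of class `fluid_state` holding the staggered
#'   velocity components, pressure, and the previous-step fields used by
#'   the second-order time integrator.
#' @export
fluid_state <- function(mesh, time = 0) {
  nz <- mesh$nz; nr <- mesh$nr
  structure(list(vz = matrix(0, nz + 1, nr),
                 vr = matrix(0, nz, nr + 1),
                 p = matrix(0, nz, nr),
                 vz_prev = matrix(0, nz + 1, nr),
                 vr_prev = matrix(0, nz, nr + 1),
                 time = time, nstep = 0L,
                 inner_iterations = 0L, residual = 0,
                 div_residual = 0,
                 eta_c = matrix(NA_real_, nz, nr)),
            class = "fluid_state")
}

# expand a scalar mean inlet velocity into the per-cell inlet profile
inlet_profile_vec <- function(inlet_velocity, mesh, config, t) {
  if (length(inlet_velocity) == mesh$nr) return(inlet_velocity)
  stopifnot(length(inlet_velocity) == 1L)
  if (is.function(config$inlet_profile))
    return(config$inlet_profile(mesh$xi_c, t))
  shape <- switch(config$inlet_profile,
                  plug = rep(1, mesh$nr),
                  parabolic = 2 * (1 - mesh$xi_c^2))
  inlet_velocity * shape
}

#' Advance the fluid one time step
#'
#' One implicit step of the coupled artery/microcirculation system on
#' the current (possibly deformed) mesh: ALE convection with the mesh
#' velocity carried by `mesh`, Carreau-Yasuda viscosity evaluated at the
#' intrinsic shear rate, Brinkman sink and volume-fraction scaling in
#' the porous zone.  Momentum and continuity are solved monolithically;
#' convection and viscosity are iterated to self-consistency within the
#' step until the residuals fall below the configured tolerance.
#' Boundary conditions: imposed inlet velocity profile, `p = 0` beyond
#' the porous outlet, symmetry on the axis, no-slip walls (the artery
#' wall moves radially with `wall_velocity`).
#'
#' @param state The [fluid_state()] at time t(n).
#' @param mesh The mesh at t(n+1) (deform first via [deform_mesh()]).
#' @param inlet_velocity Mean inlet velocity (m/s, scalar; shaped by the
#'   configured profile) or a full per-cell inlet vector.
#' @param rheology A [rheology_params()].
#' @param porous A [porous_params()].
#' @param config A [solver_config()].
#' @param wall_velocity Radial wall velocity (m/s) per artery-zone
#'   column (default all zero / rigid).
#' @return The `fluid_state` at t(n+1); fields `inner_iterations`,
#'   `residual` and `div_residual` record the convergence achieved.
#' @export
advance_fluid <- function(state, mesh, inlet_velocity,
                          rheology = rheology_params(),
                          porous = porous_params(),
                          config = solver_config(),
                          wall_velocity = NULL) {
  t_new <- state$time + config$dt
  inlet_vec <- inlet_profile_vec(inlet_velocity, mesh, config, t_new)
  if (any(!is.finite(inlet_vec)))
    stop("inlet velocity must be finite", call. = FALSE)
  ctx <- fluid_step_context(state, mesh, rheology, porous, config,
                            inlet_vec, t_new)
  wall_vr <- rep(0, mesh$nz)
  if (!is.null(wall_velocity)) {
    stopifnot(length(wall_velocity) %in% c(mesh$nz_art, mesh$nz))
    wall_vr[seq_along(wall_velocity)] <- wall_velocity
  }
  fluid_solve_step(ctx, wall_vr)
}

#' Wall-normal fluid traction on the artery wall
#'
#' Radial traction (Pa) exerted by the fluid on the compliant wall per
#' artery-zone axial station: the pressure extrapolated to the wall plus
#' the viscous normal stress \eqn{-2\eta\,\partial u_r/\partial r}
#' (negligible for near-parallel flow but retained).
#'
#' @param state A converged [fluid_state()].
#' @param mesh The matching mesh.
#' @param rheology A [rheology_params()] (used when the state carries no
#'   viscosity field).
#' @return Numeric vector of length `mesh$nz_art`.
#' @export
wall_traction <- function(state, mesh, rheology = rheology_params()) {
  gp <- mesh_geom_pack(mesh)
  nz <- gp$nz; nr <- gp$nr
  ia <- seq_len(mesh$nz_art)
  # linear extrapolation of p to the wall
  p1 <- state$p[, nr]; p2 <- state$p[, nr - 1]
  w <- (gp$Rw_c - gp$rc[, nr]) / (gp$rc[, nr] - gp$rc[, nr - 1])
  p_wall <- p1 + (p1 - p2) * w
  eta_w <- if (all(is.na(state$eta_c))) {
    gam <- shear_rate_field(state$vz, state$vr, gp)
    matrix(carreau_yasuda_viscosity(as.vector(gam), rheology), nz, nr)[, nr]
  } else state$eta_c[, nr]
  dvr_dr <- (state$vr[, nr + 1] - state$vr[, nr]) /
    (gp$Rw_c - gp$rf[, nr])
  (p_wall - 2 * eta_w * dvr_dr)[ia]
}

# one-sided second-order wall gradient of the column-averaged axial
# velocity; returns the full nz-length vector
wall_velocity_gradient <- function(state, mesh) {
  gp <- mesh_geom_pack(mesh)
  nz <- gp$nz; nr <- gp$nr
  vzc <- 0.5 * (state$vz[-1, , drop = FALSE] +
                  state$vz[-(nz + 1), , drop = FALSE])
  r1 <- gp$rc[, nr - 1]; r2 <- gp$rc[, nr]; r3 <- gp$Rw_c
  u1 <- vzc[, nr - 1]; u2 <- vzc[, nr]                 # u3 = 0 at the wall
  u1 * (r3 - r2) / ((r1 - r2) * (r1 - r3)) +
    u2 * (r3 - r1) / ((r2 - r1) * (r2 - r3))
}

#' Wall shear stress along the wall
#'
#' \eqn{\tau_w = \eta(\dot\gamma_w)\,\dot\gamma_w} with the wall shear
#' rate from a one-sided second-order finite difference of the axial
#' velocity on the deformed mesh (the axial gradient of the radial
#' velocity is negligible at the wall of a straight tube and omitted).
#'
#' @param state A [fluid_state()].
#' @param mesh The matching mesh.
#' @param rheology A [rheology_params()].
#' @param eta_override Fixed Newtonian viscosity (Pa s) or `NULL`.
#' @return WSS (Pa, >= 0) per axial column (length `mesh$nz`).
#' @export
wall_shear_stress <- function(state, mesh, rheology = rheology_params(),
                              eta_override = NULL) {
  gam_w <- abs(wall_velocity_gradient(state, mesh))
  eta <- if (is.null(eta_override))
    carreau_yasuda_viscosity(gam_w, rheology) else eta_override
  eta * gam_w
}

#' Artery/microcirculation interface diagnostics
#'
#' Reports the volumetric flux on the artery side of the zone interface,
#' the superficial flux on the porous side, and the interface pressure
#' jump (both sides extrapolated to the interface plane).  The scheme
#' enforces flux and pressure continuity, so the relative flux mismatch
#' and the normalized pressure jump are solution-quality diagnostics.
#'
#' @param state A [fluid_state()].
#' @param mesh The matching mesh (must contain both zones).
#' @param porous A [porous_params()].
#' @return A list with `flux_artery`, `flux_porous` (m3/s), `flux_mismatch`
#'   (relative), `pressure_jump` (Pa) and `pressure_jump_rel`.
#' @export
zone_interface_fluxes <- function(state, mesh, porous = porous_params()) {
  if (mesh$nz_art == 0 || mesh$nz_art == mesh$nz)
    stop("interface diagnostics need both zones present", call. = FALSE)
  gp <- mesh_geom_pack(mesh)
  ifc <- mesh$nz_art + 1L              # shared interface face index
  flux_at <- function(i) 2 * pi * sum(state$vz[i, ] * gp$Az[i, ])
  # fluxes on the faces straddling the interface; they differ only by
  # the storage rate inside the adjacent half-cells
  q_art <- flux_at(ifc - 1L)
  q_por <- flux_at(ifc + 1L)
  q_ifc <- flux_at(ifc)
  scale <- max(abs(q_ifc), abs(q_art), abs(q_por))
  mism <- if (scale > 0) abs(q_art - q_por) / scale else 0
  # pressure extrapolated to the interface plane from either side
  z_if <- mesh$zf[ifc]
  pm <- rowSums(state$p * gp$rc * (gp$rf[, -1, drop = FALSE] -
                                     gp$rf[, -(mesh$nr + 1), drop = FALSE])) /
    rowSums(gp$rc * (gp$rf[, -1, drop = FALSE] -
                       gp$rf[, -(mesh$nr + 1), drop = FALSE]))
  ia <- mesh$nz_art
  p_art <- pm[ia] + (pm[ia] - pm[ia - 1]) *
    (z_if - gp$zc[ia]) / (gp$zc[ia] - gp$zc[ia - 1])
  p_por <- pm[ia + 1] - (pm[ia + 2] - pm[ia + 1]) *
    (gp$zc[ia + 1] - z_if) / (gp$zc[ia + 2] - gp$zc[ia + 1])
  p_scale <- max(abs(pm), 1e-300)
  list(flux_artery = q_art, flux_porous = q_por,
       flux_interface = q_ifc, flux_mismatch = mism,
       pressure_jump = p_art - p_por,
       pressure_jump_rel = abs(p_art - p_por) / p_scale)
}
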