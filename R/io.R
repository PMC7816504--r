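#' Write / read a simulation configuration as YAML
#'
#' Serialises every numeric/character setting of a
#' [simulation_config()] to a plain-text YAML file and restores it
#' through the package constructors (so all invariants are re-checked on
#' read).  Function-valued settings (`body_force`, a functional inlet
#' profile) are not representable in YAML and are rejected.
#'
#' @param config A [simulation_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns the restored `simulation_config`.
#' @export
write_config <- function(config, path) {
  if (is.function(config$solver$inlet_profile) ||
      !is.null(config$solver$body_force))
    stop("function-valued solver settings cannot be serialised",
         call. = FALSE)
  strip <- function(x) lapply(unclass(x), function(v) v)
  out <- list(geometry = strip(config$geometry),
              rheology = strip(config$rheology),
              porous = strip(config$porous),
              wall = strip(config$wall),
              waveform = strip(config$waveform),
              solver = strip(config$solver)[
                c("dt", "residual_tol", "max_inner_iterations",
                  "advection", "inlet_profile", "startup_ramp")],
              coupling = strip(config$coupling),
              mesh = list(nz = config$nz, nr = config$nr,
                          wall_cluster = config$wall_cluster))
  out$geometry$section_positions <- as.list(config$geometry$section_positions)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- if (!is.null(y$geometry$section_positions))
    unlist(y$geometry$section_positions) else NULL
  geometry <- geometry_config(radius = y$geometry$radius,
                              wall_thickness = y$geometry$wall_thickness,
                              artery_length = y$geometry$artery_length,
                              micro_length = y$geometry$micro_length,
                              section_positions = sp)
  simulation_config(
    geometry = geometry,
    rheology = do.call(rheology_params, y$rheology),
    porous = do.call(porous_params, y$porous),
    wall = do.call(wall_params, y$wall),
    waveform = do.call(waveform_config, y$waveform),
    solver = do.call(solver_config, y$solver),
    coupling = do.call(coupling_config, y$coupling),
    nz = y$mesh$nz, nr = y$mesh$nr, wall_cluster = y$mesh$wall_cluster)
}

#' Export run results as CSV tables (plus a config provenance file)
#'
#' Writes `probes.csv` (per-step section series), `summary.csv`
#' (analysis-cycle extrema), `wall_displacement.csv` and `config.yaml`
#' into `dir`.
#'
#' @param run A [run_simulation()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run_csv <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- run$series
  cols <- list(time = ser$time)
  for (nm in names(ser$sections))
    for (f in names(ser$sections[[nm]]))
      cols[[paste(nm, f, sep = "_")]] <- ser$sections[[nm]][[f]]
  utils::write.csv(as.data.frame(cols),
                   file.path(dir, "probes.csv"), row.names = FALSE)
  utils::write.csv(run$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  wd <- as.data.frame(t(run$wall_d))
  names(wd) <- sprintf("station_%03d", seq_len(nrow(run$wall_d)))
  utils::write.csv(cbind(time = ser$time, wd),
                   file.path(dir, "wall_displacement.csv"),
                   row.names = FALSE)
  cfg <- run$config
  if (!is.function(cfg$solver$inlet_profile) &&
      is.null(cfg$solver$body_force))
    write_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write a legacy-ASCII VTK snapshot of the flow field
#'
#' Structured-grid file (r-z plane, one cell thick in the third
#' direction) with cell data `pressure`, `vz`, `vr`, `viscosity` and
#' `zone`; loadable in ParaView for inspection.
#'
#' @param state A [fluid_state()].
#' @param mesh The matching mesh.
#' @param file Output path (conventionally `.vtk`).
#' @return `file`, invisibly.
#' @export
write_vtk_snapshot <- function(state, mesh, file) {
  gp <- mesh_geom_pack(mesh)
  nz <- gp$nz; nr <- gp$nr
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("hemofsi snapshot t=%.6f", state$time),
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nz + 1, nr + 1),
               sprintf("POINTS %d double", (nz + 1) * (nr + 1))), con)
  pts <- matrix(0, (nz + 1) * (nr + 1), 3)
  k <- 1
  for (j in 1:(nr + 1)) for (i in 1:(nz + 1)) {
    pts[k, ] <- c(gp$zf[i], gp$xi_f[j] * gp$Rw_f[i], 0)
    k <- k + 1
  }
  utils::write.table(format(pts, digits = 9, scientific = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  vzc <- 0.5 * (state$vz[-1, , drop = FALSE] +
                  state$vz[-(nz + 1), , drop = FALSE])
  vrc <- 0.5 * (state$vr[, -1, drop = FALSE] +
                  state$vr[, -(nr + 1), drop = FALSE])
  writeLines(sprintf("CELL_DATA %d", nz * nr), con)
  wfield <- function(name, m) {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(m), digits = 9, scientific = TRUE), con)
  }
  wfield("pressure", state$p)
  wfield("vz", vzc)
  wfield("vr", vrc)
  if (!all(is.na(state$eta_c))) wfield("viscosity", state$eta_c)
  wfield("zone", matrix(as.numeric(mesh$zone == "micro"), nz, nr))
  invisible(file)
}
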