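#' Geometry of the two-zone axisymmetric domain
#'
#' A straight tube of lumen radius R = D/2 made of an artery zone
#' (compliant wall, length `artery_length`) followed by a microcirculation
#' seepage zone (rigid wall, length `micro_length`).  Probe sections S1
#' and S2 sit in the artery zone, S3 and S4 in the porous zone; defaults
#' place them at 25% / 75% of each zone's length.
#'
#' @param radius Lumen radius R (m); default 0.010 (20 mm diameter).
#' @param wall_thickness Arterial wall thickness (m); default 0.002.
#' @param artery_length Artery-zone length (m); default 0.200 (10 D).
#' @param micro_length Microcirculation-zone length (m); default 0.100
#'   (5 D).  Either zone length may be 0 for degenerate single-zone
#'   verification domains (probes of the absent zone are dropped).
#' @param section_positions Named numeric vector of absolute axial probe
#'   positions (m) for `S1, S2, S3, S4`; `NULL` uses the 25/75% defaults.
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(radius = 0.010, wall_thickness = 0.002,
                            artery_length = 0.200, micro_length = 0.100,
                            section_positions = NULL) {
  if (radius <= 0 || wall_thickness <= 0)
    stop("radius and wall_thickness must be > 0", call. = FALSE)
  if (artery_length < 0 || micro_length < 0)
    stop("zone lengths must be >= 0", call. = FALSE)
  if (artery_length + micro_length <= 0)
    stop("artery_length: domain must have positive length", call. = FALSE)
  if (is.null(section_positions)) {
    section_positions <- c(S1 = 0.25 * artery_length,
                           S2 = 0.75 * artery_length,
                           S3 = artery_length + 0.25 * micro_length,
                           S4 = artery_length + 0.75 * micro_length)
    if (artery_length == 0) section_positions <- section_positions[c("S3", "S4")]
    if (micro_length == 0) section_positions <- section_positions[c("S1", "S2")]
  }
  L <- artery_length + micro_length
  if (any(section_positions < 0 | section_positions > L))
    stop("section_positions must lie inside the domain", call. = FALSE)
  structure(list(radius = radius, wall_thickness = wall_thickness,
                 artery_length = artery_length, micro_length = micro_length,
                 section_positions = section_positions),
            class = "geometry_config")
}

#' Build the structured axisymmetric mesh
#'
#' Staggered (MAC) finite-volume grid: pressures at cell centres, axial
#' velocity on axial faces, radial velocity on radial faces.  The axial
#' grid is piecewise uniform with a face exactly on the artery/
#' microcirculation interface; the radial grid is a normalized template
#' \eqn{\xi \in [0,1]} (optionally tanh-clustered toward the wall) scaled
#' by the local wall radius, so ALE deformation is a pure radial
#' stretching per column.
#'
#' @param geometry A [geometry_config()].
#' @param nz Total axial cell count (>= 20).
#' @param nr Radial cell count (>= 8).
#' @param wall_cluster Tanh clustering strength toward the wall; 0 gives
#'   a uniform radial grid, the default 1.5 refines the wall cells about
#'   2.4x to resolve the oscillatory boundary layer.
#' @return An object of class `hemo_mesh`.
#' @export
build_mesh <- function(geometry, nz = 150, nr = 24, wall_cluster = 1.5) {
  if (nz < 20) stop("nz must be >= 20", call. = FALSE)
  if (nr < 8) stop("nr must be >= 8", call. = FALSE)
  g <- geometry
  L <- g$artery_length + g$micro_length
  # split columns proportionally, interface on a face
  nz_art <- if (g$artery_length == 0) 0L else if (g$micro_length == 0) nz else
    max(1L, min(nz - 1L, round(nz * g$artery_length / L)))
  nz_mic <- nz - nz_art
  zf <- c(if (nz_art > 0) seq(0, g$artery_length, length.out = nz_art + 1)
          else 0,
          if (nz_mic > 0)
            seq(g$artery_length, L, length.out = nz_mic + 1)[-1])
  zc <- 0.5 * (zf[-1] + zf[-(nz + 1)])
  dz <- diff(zf)
  s <- seq(0, 1, length.out = nr + 1)
  xi_f <- if (wall_cluster > 0)
    1 - tanh(wall_cluster * (1 - s)) / tanh(wall_cluster) else s
  xi_c <- 0.5 * (xi_f[-1] + xi_f[-(nr + 1)])
  zone <- c(rep("artery", nz_art), rep("micro", nz_mic))
  probes <- vapply(g$section_positions, function(z0) which.min(abs(zc - z0)),
                   integer(1))
  structure(list(nz = nz, nr = nr, nz_art = nz_art,
                 zf = zf, zc = zc, dz = dz,
                 xi_f = xi_f, xi_c = xi_c,
                 R0 = g$radius,
                 Rw_c = rep(g$radius, nz),
                 Rw_prev_c = rep(g$radius, nz),
                 wall_rate_c = rep(0, nz),
                 d_c = numeric(max(nz_art, 1L))[seq_len(nz_art)],
                 zone = zone, probes = probes,
                 geometry = g),
            class = "hemo_mesh")
}

#' @export
print.hemo_mesh <- function(x, ...) {
  cat(sprintf("<hemo_mesh> %d x %d cells (%d artery + %d micro columns)\n",
              x$nz, x$nr, x$nz_art, x$nz - x$nz_art))
  cat(sprintf("  R = %.4g m, L = %.4g m, probes at z = %s\n", x$R0,
              max(x$zf), paste(signif(x$zc[x$probes], 3), collapse = ", ")))
  invisible(x)
}

#' Deform the mesh to a new wall displacement
#'
#' Algebraic radial stretching: every node of an artery-zone column moves
#' to \eqn{r = \xi (R + d(z))}; microcirculation columns never move.  The
#' wall rate `(d - d_prev)/dt` (backward difference) defines the radial
#' mesh velocity \eqn{u_m = \xi \, \dot R_w(z)} used by the ALE
#' convection terms.
#'
#' @param mesh A [build_mesh()] result.
#' @param wall_displacement Radial wall displacement d (m), one value per
#'   artery-zone column; must stay below half the radius.
#' @param dt Time step (s) behind the backward difference.
#' @param previous_displacement Displacement at the previous time level;
#'   defaults to the displacement currently stored in `mesh`.
#' @return The deformed `hemo_mesh` (with `wall_rate_c` updated).
#' @export
deform_mesh <- function(mesh, wall_displacement, dt,
                        previous_displacement = NULL) {
  nz_art <- mesh$nz_art
  stopifnot(length(wall_displacement) == nz_art)
  if (any(abs(wall_displacement) >= 0.5 * mesh$R0))
    stop("wall displacement exceeded half the radius: FSI divergence",
         call. = FALSE)
  if (is.null(previous_displacement)) previous_displacement <- mesh$d_c
  d_prev_full <- c(previous_displacement, rep(0, mesh$nz - nz_art))
  d_full <- c(wall_displacement, rep(0, mesh$nz - nz_art))
  mesh$Rw_prev_c <- mesh$R0 + d_prev_full
  mesh$Rw_c <- mesh$R0 + d_full
  mesh$wall_rate_c <- (d_full - d_prev_full) / dt
  mesh$d_c <- wall_displacement
  mesh
}

#' Fluid-domain volume of the mesh
#'
#' Sum of cell volumes \eqn{2\pi r \, \Delta r \, \Delta z}; cells of the
#' microcirculation zone are weighted by `area_expansion`, the effective
#' cross-section multiplier of the capillary bed.
#'
#' @param mesh A `hemo_mesh`.
#' @param area_expansion Porous-zone cross-section multiplier (>= 1).
#' @return Volume (m3).
#' @export
mesh_volume <- function(mesh, area_expansion = 1) {
  w <- ifelse(mesh$zone == "micro", area_expansion, 1)
  # per column: sum_j pi (xi_f[j+1]^2 - xi_f[j]^2) Rw^2 dz = pi Rw^2 dz
  sum(w * pi * mesh$Rw_c^2 * mesh$dz)
}
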