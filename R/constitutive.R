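#' Blood rheology parameters
#'
#' Container for the Carreau-Yasuda shear-thinning constants and the fluid
#' density.  Defaults are the standard blood values used throughout the
#' package: \eqn{\eta_\infty = 2.2\times 10^{-3}} Pa s,
#' \eqn{\eta_0 = 22\times 10^{-3}} Pa s, \eqn{\lambda = 0.110} s,
#' \eqn{a = 0.644}, \eqn{n = 0.392}, \eqn{\rho = 1050} kg/m3.
#'
#' @param eta_inf Infinite-shear viscosity (Pa s).
#' @param eta_0 Zero-shear viscosity (Pa s); must exceed `eta_inf`.
#' @param lambda_relax Relaxation time (s) setting the shear-rate scale of
#'   the shear-thinning transition.
#' @param a_exp Yasuda transition-width exponent (dimensionless, > 0).
#' @param n_exp Power-law index (dimensionless, in (0, 1]); `n_exp = 1`
#'   gives a Newtonian fluid of viscosity `eta_0`.
#' @param rho_fluid Blood density (kg/m3).
#'
#' @return An object of class `rheology_params`.
#' @export
#' @examples
#' rp <- rheology_params()
#' carreau_yasuda_viscosity(c(0, 10, 1e4), rp)
rheology_params <- function(eta_inf = 2.2e-3, eta_0 = 22e-3,
                            lambda_relax = 0.110, a_exp = 0.644,
                            n_exp = 0.392, rho_fluid = 1050) {
  stopifnot(is.numeric(eta_inf), is.numeric(eta_0), is.numeric(lambda_relax),
            is.numeric(a_exp), is.numeric(n_exp), is.numeric(rho_fluid))
  if (!(eta_0 > eta_inf && eta_inf > 0))
    stop("must have eta_0 > eta_inf > 0", call. = FALSE)
  if (lambda_relax <= 0) stop("lambda_relax must be > 0", call. = FALSE)
  if (a_exp <= 0) stop("a_exp must be > 0", call. = FALSE)
  if (n_exp <= 0 || n_exp > 1) stop("n_exp must be in (0, 1]", call. = FALSE)
  if (rho_fluid <= 0) stop("rho_fluid must be > 0", call. = FALSE)
  structure(list(eta_inf = eta_inf, eta_0 = eta_0,
                 lambda_relax = lambda_relax, a_exp = a_exp, n_exp = n_exp,
                 rho_fluid = rho_fluid),
            class = "rheology_params")
}

#' Porous microcirculation parameters
#'
#' Parameters of the Darcy-Brinkman seepage zone that terminates the
#' artery.  The permeability defaults to the Kozeny-Carman value
#' [kozeny_carman_permeability()] for the given microvessel diameter and
#' porosity, and may be overridden to calibrate the terminal resistance.
#'
#' `area_expansion` scales the effective cross-section of the
#' microcirculation bed relative to the artery lumen.  The capillary bed
#' drains a far larger total cross-section than the feeding artery; with
#' `area_expansion = A` the tube-frame superficial velocity in the porous
#' zone corresponds to an intrinsic pore velocity `v / (porosity * A)` and
#' the terminal Darcy resistance scales as `1 / A`.  The neutral value 1
#' represents a uniform tube.
#'
#' @param porosity Porosity \eqn{\phi} of the bed, in (0, 1).
#' @param microvessel_diameter Characteristic microvessel diameter d (m).
#' @param permeability Permeability k (m2); `NULL` (default) derives it
#'   from `d` and `phi` by the Kozeny-Carman relation.
#' @param area_expansion Effective cross-section of the microcirculation
#'   zone relative to the artery lumen (dimensionless >= 1).
#' @param viscosity_mode How the viscosity entering the Brinkman drag is
#'   evaluated: `"local"` uses the local Carreau-Yasuda viscosity at the
#'   resolved shear rate; `"eta_inf"` uses the constant infinite-shear
#'   viscosity.
#'
#' @return An object of class `porous_params`.
#' @export
#' @examples
#' porous_params()$permeability        # Kozeny-Carman default
porous_params <- function(porosity = 0.5, microvessel_diameter = 8e-6,
                          permeability = NULL, area_expansion = 1,
                          viscosity_mode = c("local", "eta_inf")) {
  viscosity_mode <- match.arg(viscosity_mode)
  if (!(porosity > 0 && porosity < 1))
    stop("porosity must lie in (0, 1)", call. = FALSE)
  if (microvessel_diameter <= 0)
    stop("microvessel_diameter must be > 0", call. = FALSE)
  if (area_expansion < 1)
    stop("area_expansion must be >= 1", call. = FALSE)
  k <- if (is.null(permeability))
    kozeny_carman_permeability(microvessel_diameter, porosity)
  else permeability
  if (k <= 0) stop("permeability must be > 0", call. = FALSE)
  structure(list(porosity = porosity,
                 microvessel_diameter = microvessel_diameter,
                 permeability = k, area_expansion = area_expansion,
                 viscosity_mode = viscosity_mode),
            class = "porous_params")
}

#' Carreau-Yasuda viscosity
#'
#' Shear-thinning apparent viscosity
#' \deqn{\eta(\dot\gamma) = \eta_\infty + (\eta_0-\eta_\infty)
#'       \left[1+(\lambda\dot\gamma)^a\right]^{(n-1)/a}.}
#' The result decreases monotonically from \eqn{\eta_0} at zero shear to
#' \eqn{\eta_\infty} at infinite shear.
#'
#' @param gamma_dot Shear-rate magnitude (1/s), vectorised, >= 0.
#' @param params A [rheology_params()] object.
#' @return Viscosity (Pa s), same length as `gamma_dot`.
#' @export
carreau_yasuda_viscosity <- function(gamma_dot, params = rheology_params()) {
  if (any(gamma_dot < 0, na.rm = TRUE))
    stop("gamma_dot must be non-negative", call. = FALSE)
  p <- params
  p$eta_inf + (p$eta_0 - p$eta_inf) *
    (1 + (p$lambda_relax * gamma_dot)^p$a_exp)^((p$n_exp - 1) / p$a_exp)
}

#' Scalar shear-rate magnitude of an axisymmetric velocity gradient
#'
#' Second-invariant shear rate \eqn{\dot\gamma = \sqrt{2\,D:D}} of the
#' symmetric strain-rate tensor on an axisymmetric (r, z) field, including
#' the hoop component \eqn{u_r/r}:
#' \deqn{\dot\gamma^2 = 2\left[(\partial_z u_z)^2 + (\partial_r u_r)^2 +
#'   (u_r/r)^2\right] + (\partial_r u_z + \partial_z u_r)^2.}
#'
#' @param duz_dz,dur_dr,hoop,duz_dr,dur_dz Velocity-gradient components
#'   (1/s); `hoop` is \eqn{u_r/r}.  All vectorised.
#' @return Shear-rate magnitude (1/s).
#' @export
#' @examples
#' shear_rate_magnitude(duz_dr = 5)   # pure axial shear -> 5
shear_rate_magnitude <- function(duz_dz = 0, dur_dr = 0, hoop = 0,
                                 duz_dr = 0, dur_dz = 0) {
  if (any(!is.finite(c(duz_dz, dur_dr, hoop, duz_dr, dur_dz))))
    stop("velocity-gradient components must be finite", call. = FALSE)
  sqrt(2 * (duz_dz^2 + dur_dr^2 + hoop^2) + (duz_dr + dur_dz)^2)
}

#' Kozeny-Carman permeability
#'
#' Empirical permeability of a porous bed of characteristic pore diameter
#' d and porosity \eqn{\phi}:
#' \deqn{k = \frac{d^2 \phi^3}{180 (1-\phi)^2}.}
#'
#' @param d Microvessel (pore) diameter (m), > 0.
#' @param phi Porosity, in (0, 1).
#' @return Permeability (m2).
#' @export
#' @examples
#' kozeny_carman_permeability(8e-6, 0.5)   # ~1.78e-13 m2
kozeny_carman_permeability <- function(d, phi) {
  if (any(phi <= 0 | phi >= 1))
    stop("phi must lie in (0, 1)", call. = FALSE)
  if (any(d <= 0)) stop("d must be > 0", call. = FALSE)
  d^2 * phi^3 / (180 * (1 - phi)^2)
}

#' Brinkman momentum-sink coefficient
#'
#' Multiplier of the intrinsic (pore) velocity in the porous momentum
#' sink \eqn{-(\phi^2\eta/k)\,u}.  With \eqn{\phi = 1} the sink reduces to
#' the classical Darcy drag \eqn{\eta/k} on the superficial velocity.
#'
#' @param phi Porosity, in (0, 1].
#' @param eta Dynamic viscosity (Pa s), > 0.
#' @param k Permeability (m2), > 0.
#' @return Sink coefficient (Pa s / m2).
#' @export
brinkman_sink_coefficient <- function(phi, eta, k) {
  if (any(k <= 0)) stop("permeability k must be > 0", call. = FALSE)
  if (any(phi <= 0) || any(eta <= 0))
    stop("phi and eta must be > 0", call. = FALSE)
  phi^2 * eta / k
}
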