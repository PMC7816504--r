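#' Probe time series container
#'
#' Uniformly sampled per-section time series recorded during a run:
#' section pressure (area-weighted mean over the cross-section), peak
#' axial velocity over the section radius, and the wall shear stress at
#' the axially matching wall station.
#'
#' @param time Time vector (s), uniformly spaced.
#' @param sections Named list (`S1`, `S2`, ...); each element a list with
#'   numeric vectors `pressure`, `velocity`, `wss` of `length(time)`.
#' @return An object of class `probe_series`.
#' @export
probe_series <- function(time, sections) {
  stopifnot(length(time) >= 2)
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("probe series must be uniformly sampled", call. = FALSE)
  for (s in sections)
    stopifnot(all(vapply(s, length, 1L) == length(time)))
  structure(list(time = time, dt = dt[1], sections = sections),
            class = "probe_series")
}

#' Extract one cycle from a probe series
#'
#' Returns the sub-series covering `((k-1) T, k T]` for cycle index k,
#' the protocol used to discard start-up transients (run several cycles,
#' analyse the last).
#'
#' @param series A [probe_series()].
#' @param cycle_index Cycle number k (1-based).
#' @param period Cycle period T (s).
#' @return A `probe_series` of `period / dt` samples.
#' @export
extract_cycle <- function(series, cycle_index, period) {
  n_per <- round(period / series$dt)
  idx <- which(series$time > (cycle_index - 1) * period - 1e-9 * series$dt &
                 series$time <= cycle_index * period + 1e-9 * series$dt)
  if (length(idx) < n_per)
    stop(sprintf("series does not span cycle %d", cycle_index),
         call. = FALSE)
  idx <- utils::tail(idx, n_per)
  sec <- lapply(series$sections, function(s) lapply(s, function(v) v[idx]))
  probe_series(series$time[idx], sec)
}

#' Per-cycle extrema summary
#'
#' Peak pressure, bottom pressure, pressure amplitude (peak - bottom),
#' peak sectional velocity and peak wall shear stress for every section
#' of a (single-cycle) probe series.
#'
#' @param series A [probe_series()] covering the cycle to summarise.
#' @param cycle Optional cycle index stored in the output for bookkeeping.
#' @return A data frame with one row per section, class `cycle_summary`.
#' @export
cycle_summary <- function(series, cycle = NA_integer_) {
  rows <- lapply(names(series$sections), function(nm) {
    s <- series$sections[[nm]]
    data.frame(section = nm,
               peak_pressure = max(s$pressure),
               bottom_pressure = min(s$pressure),
               pressure_amplitude = max(s$pressure) - min(s$pressure),
               peak_velocity = max(s$velocity),
               peak_wss = max(s$wss),
               cycle = cycle)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cycle_summary", "data.frame")
  out
}

#' Compare two cycle summaries (compliant vs rigid)
#'
#' Per-section differences (`compliant - rigid`) and ratios
#' (`compliant / rigid`) of the peak pressure, peak velocity and peak
#' wall shear stress.  Antisymmetric under argument swap (deltas negate,
#' ratios invert).
#'
#' @param compliant,rigid [cycle_summary()] data frames over the same
#'   sections.
#' @return A data frame of deltas and ratios per section.
#' @export
compare_runs <- function(compliant, rigid) {
  if (!identical(compliant$section, rigid$section))
    stop("section sets differ between the two summaries", call. = FALSE)
  data.frame(section = compliant$section,
             d_peak_pressure = compliant$peak_pressure - rigid$peak_pressure,
             d_peak_velocity = compliant$peak_velocity - rigid$peak_velocity,
             d_peak_wss = compliant$peak_wss - rigid$peak_wss,
             r_peak_pressure = compliant$peak_pressure / rigid$peak_pressure,
             r_peak_velocity = compliant$peak_velocity / rigid$peak_velocity,
             r_peak_wss = compliant$peak_wss / rigid$peak_wss)
}

# Bessel J0/J1 for complex argument by the ascending series; adequate to
# ~1e-9 relative for |z| <= 30, which covers Womersley numbers up to ~30.
besselJ_complex <- function(z, nu) {
  stopifnot(nu %in% c(0, 1))
  term <- (z / 2)^nu / ifelse(nu == 1, 1, 1)   # k = 0 term (0! (0+nu)! = 1)
  total <- term
  zz <- -(z / 2)^2
  for (k in 1:80) {
    term <- term * zz / (k * (k + nu))
    total <- total + term
  }
  total
}

#' Womersley oscillatory pipe-flow solution
#'
#' Classical analytic solution for fully developed laminar flow of a
#' Newtonian fluid in a rigid circular tube driven by an oscillating
#' axial pressure gradient \eqn{-\partial p/\partial z = G\cos(\omega t)}:
#' \deqn{u(r,t)=\Re\left[\frac{G}{i\rho\omega}
#'  \left(1-\frac{J_0(\Lambda r/R)}{J_0(\Lambda)}\right)e^{i\omega t}\right],
#'  \qquad \Lambda = i^{3/2}\,\alpha,\quad
#'  \alpha = R\sqrt{\omega\rho/\eta}.}
#' Used as the independent verification oracle for the unsteady fluid
#' solver (it is not part of the simulated model).
#'
#' @param R Tube radius (m).
#' @param rho Fluid density (kg/m3).
#' @param eta Dynamic viscosity (Pa s).
#' @param pressure_gradient_amplitude G (Pa/m).
#' @param omega Angular frequency (rad/s).
#' @param r Radial positions (m), `<= R`.
#' @param t Times (s); recycled against `r` by outer combination when both
#'   have length > 1? No: `r` and `t` must be equal length or length 1.
#' @return Axial velocity (m/s).
#' @seealso [womersley_wall_shear_amplitude()], [womersley_mean_amplitude()]
#' @export
womersley_solution <- function(R, rho, eta, pressure_gradient_amplitude,
                               omega, r, t) {
  if (any(r > R + 1e-12)) stop("r must be <= R", call. = FALSE)
  alpha <- R * sqrt(omega * rho / eta)
  Lam <- complex(modulus = alpha, argument = 3 * pi / 4)   # i^{3/2} alpha
  G <- pressure_gradient_amplitude
  prof <- 1 - besselJ_complex(Lam * r / R, 0) / besselJ_complex(Lam, 0)
  Re((G / (1i * rho * omega)) * prof * exp(1i * omega * t))
}

#' @rdname womersley_solution
#' @details `womersley_wall_shear_amplitude` returns the amplitude of the
#'   oscillating wall shear stress \eqn{\eta\,\partial u/\partial r|_{r=R}},
#'   and `womersley_mean_amplitude` the amplitude of the cross-section
#'   mean velocity; both with a `phase` attribute (radians relative to
#'   the pressure-gradient phase).
#' @export
womersley_wall_shear_amplitude <- function(R, rho, eta,
                                           pressure_gradient_amplitude,
                                           omega) {
  alpha <- R * sqrt(omega * rho / eta)
  Lam <- complex(modulus = alpha, argument = 3 * pi / 4)
  G <- pressure_gradient_amplitude
  tau <- eta * (G / (1i * rho * omega)) * (-Lam / R) *
    besselJ_complex(Lam, 1) / besselJ_complex(Lam, 0)
  structure(Mod(tau), phase = Arg(tau))
}

#' @rdname womersley_solution
#' @export
womersley_mean_amplitude <- function(R, rho, eta,
                                     pressure_gradient_amplitude, omega) {
  alpha <- R * sqrt(omega * rho / eta)
  Lam <- complex(modulus = alpha, argument = 3 * pi / 4)
  G <- pressure_gradient_amplitude
  um <- (G / (1i * rho * omega)) *
    (1 - 2 * besselJ_complex(Lam, 1) / (Lam * besselJ_complex(Lam, 0)))
  structure(Mod(um), phase = Arg(um))
}

#' Moens-Korteweg pulse-wave speed
#'
#' Closed-form speed \eqn{c = \sqrt{E h / (2 \rho R)}} of the pressure
#' pulse in a thin elastic tube filled with incompressible fluid; the
#' verification oracle for the coupled wave dynamics.
#'
#' @param E Young's modulus (Pa).
#' @param h Wall thickness (m).
#' @param rho Fluid density (kg/m3).
#' @param R Lumen radius (m).
#' @return Wave speed (m/s).
#' @export
#' @examples
#' moens_korteweg_speed(5e6, 0.002, 1050, 0.010)   # ~21.8 m/s
moens_korteweg_speed <- function(E, h, rho, R) {
  stopifnot(E > 0, h > 0, rho > 0, R > 0)
  sqrt(E * h / (2 * rho * R))
}
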