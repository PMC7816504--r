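#' Inlet velocity waveform configuration
#'
#' Parametric periodic pulse standing in for a measured cardiac inlet
#' velocity trace.  The default shape puts a squared half-sine systolic
#' pulse of duration `systolic_fraction * period` on top of a constant
#' diastolic baseline:
#' \deqn{u(t) = u_{dia} + (u_{peak}-u_{dia})
#'       \sin^2\!\left(\pi t / (f_s T)\right), \quad 0 \le t < f_s T,}
#' and \eqn{u(t) = u_{dia}} for the rest of the cycle.  The waveform is
#' continuous and once differentiable, with cycle mean
#' \eqn{u_{dia} + (u_{peak}-u_{dia}) f_s / 2}.
#'
#' `peak_velocity` is a *mean-over-the-cross-section* velocity scale: the
#' imposed inlet profile (plug or parabolic, see [solver_config()])
#' multiplies it radially.  It is the natural calibration handle for
#' matching a published sectional peak velocity.
#'
#' @param period Cardiac period T (s).
#' @param peak_velocity Systolic peak of the mean inlet velocity (m/s).
#' @param diastolic_velocity Diastolic baseline mean velocity (m/s).
#' @param systolic_fraction Fraction of the period occupied by systole.
#' @param profile_shape `"half_sine_squared"` (default) or `"fourier"`
#'   (same pulse smoothed by its first 8 Fourier harmonics, giving a
#'   slightly rounded foot).
#' @return An object of class `waveform_config`.
#' @export
waveform_config <- function(period = 0.8, peak_velocity = 0.75,
                            diastolic_velocity = 0.05,
                            systolic_fraction = 0.4,
                            profile_shape = c("half_sine_squared",
                                              "fourier")) {
  profile_shape <- match.arg(profile_shape)
  if (period <= 0) stop("period must be > 0", call. = FALSE)
  if (!(peak_velocity > diastolic_velocity && diastolic_velocity >= 0))
    stop("need peak_velocity > diastolic_velocity >= 0", call. = FALSE)
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("systolic_fraction must be in (0, 1)", call. = FALSE)
  structure(list(period = period, peak_velocity = peak_velocity,
                 diastolic_velocity = diastolic_velocity,
                 systolic_fraction = systolic_fraction,
                 profile_shape = profile_shape),
            class = "waveform_config")
}

wf_closed_form <- function(t, cfg) {
  tau <- t %% cfg$period
  ts <- cfg$systolic_fraction * cfg$period
  u <- rep(cfg$diastolic_velocity, length(tau))
  sys <- tau < ts
  u[sys] <- cfg$diastolic_velocity +
    (cfg$peak_velocity - cfg$diastolic_velocity) *
    sin(pi * tau[sys] / ts)^2
  u
}

#' Generate a sampled inlet waveform
#'
#' @param config A [waveform_config()].
#' @param n_samples Samples per period (>= 16); 400 resolves the default
#'   pulse to better than 1e-6 relative.
#' @return An object of class `waveform`: time grid covering one period
#'   (first and last samples equal by periodicity), velocity samples, and
#'   a copy of the configuration.
#' @export
generate_waveform <- function(config = waveform_config(), n_samples = 400) {
  stopifnot(n_samples >= 16)
  t <- seq(0, config$period, length.out = n_samples + 1)
  u <- wf_closed_form(t, config)
  if (config$profile_shape == "fourier") {
    # project the pulse on its mean + first 8 harmonics (smooth stand-in)
    tt <- seq(0, config$period, length.out = 2049)[-2049]
    uu <- wf_closed_form(tt, config)
    co <- stats::fft(uu) / length(uu)
    keep <- 8
    u <- Re(co[1]) + rep(0, length(t))
    for (m in seq_len(keep)) {
      u <- u + 2 * Re(co[m + 1] * exp(2i * pi * m * t / config$period))
    }
    # preserve the configured peak exactly
    u <- config$diastolic_velocity +
      (u - min(u)) * (config$peak_velocity - config$diastolic_velocity) /
      (max(u) - min(u))
  }
  u[length(u)] <- u[1]
  structure(list(time = t, velocity = u, config = config,
                 analytic = config$profile_shape == "half_sine_squared"),
            class = "waveform")
}

#' Sample an inlet waveform at arbitrary times
#'
#' Periodic extension.  For the analytic default shape the closed form
#' is evaluated exactly (so the result is independent of the stored
#' sample density); waveforms defined only by samples (CSV traces, the
#' Fourier shape) are interpolated linearly.
#'
#' @param waveform A [generate_waveform()] result.
#' @param t Times (s), vectorised, >= 0.
#' @return Mean inlet velocity (m/s) at `t`.
#' @export
sample_waveform <- function(waveform, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (isTRUE(waveform$analytic)) return(wf_closed_form(t, waveform$config))
  tau <- t %% waveform$config$period
  stats::approx(waveform$time, waveform$velocity, xout = tau,
                rule = 2)$y
}

#' Read / write a waveform as two-column CSV
#'
#' Plain `time,velocity` CSV so a digitised measured trace can replace
#' the parametric generator.
#'
#' @param waveform A `waveform` object.
#' @param path File path.
#' @return `write_waveform_csv` returns `path` invisibly;
#'   `read_waveform_csv` returns a `waveform` whose config records the
#'   trace's period and extrema.
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(data.frame(time = waveform$time,
                              velocity = waveform$velocity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time", "velocity") %in% names(d)))
  cfg <- waveform_config(period = max(d$time),
                         peak_velocity = max(d$velocity),
                         diastolic_velocity = max(min(d$velocity), 0),
                         systolic_fraction = 0.4)
  structure(list(time = d$time, velocity = d$velocity, config = cfg),
            class = "waveform")
}
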