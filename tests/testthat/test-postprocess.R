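mk_series <- function(n = 200, dt = 4e-3, f = function(t) sin(2 * pi * t)) {
  t <- dt * seq_len(n)
  probe_series(t, list(
    S1 = list(pressure = 2 + 3 * f(t), velocity = abs(f(t)), wss = f(t)^2),
    S2 = list(pressure = 1 + f(t), velocity = 0.5 * abs(f(t)),
              wss = 0.5 * f(t)^2)))
}

test_that("cycle extraction partitions the series exactly", {
  ser <- mk_series(n = 600)             # 3 cycles of T = 0.8 at dt = 4e-3
  one <- extract_cycle(ser, 1, 0.8)
  expect_equal(length(one$time), 200)
  expect_equal(one$sections$S1$pressure, ser$sections$S1$pressure[1:200])
  cy3 <- extract_cycle(ser, 3, 0.8)
  expect_equal(cy3$time[200], 2.4)
  recon <- c(extract_cycle(ser, 1, 0.8)$sections$S2$wss,
             extract_cycle(ser, 2, 0.8)$sections$S2$wss,
             cy3$sections$S2$wss)
  expect_identical(recon, ser$sections$S2$wss)
  expect_error(extract_cycle(ser, 4, 0.8), "span")
  single <- mk_series(n = 200)
  expect_equal(extract_cycle(single, 1, 0.8)$sections$S1$velocity,
               single$sections$S1$velocity)
})

test_that("cycle summary computes extrema and amplitudes", {
  t <- 4e-3 * seq_len(200)
  const <- probe_series(t, list(S1 = list(pressure = rep(5, 200),
                                          velocity = rep(1, 200),
                                          wss = rep(0.2, 200))))
  s <- cycle_summary(const)
  expect_equal(s$peak_pressure, 5)
  expect_equal(s$bottom_pressure, 5)
  expect_equal(s$pressure_amplitude, 0)
  A <- 3; m <- 10
  sine <- probe_series(t, list(S1 = list(
    pressure = m + A * sin(2 * pi * t / 0.8), velocity = t * 0, wss = t * 0)))
  s2 <- cycle_summary(sine)
  expect_equal(s2$pressure_amplitude, 2 * A, tolerance = 1e-3)
  expect_equal(s2$peak_pressure, m + A, tolerance = 1e-3)
})

test_that("summary extrema are invariant to a time shift of the periodic series", {
  f <- function(t) sin(2 * pi * t / 0.8) + 0.3 * cos(4 * pi * t / 0.8)
  s1 <- cycle_summary(mk_series(f = f))
  s2 <- cycle_summary(mk_series(f = function(t) f(t + 0.27)))
  expect_equal(s1$pressure_amplitude, s2$pressure_amplitude, tolerance = 5e-3)
  expect_equal(s1$peak_wss, s2$peak_wss, tolerance = 5e-3)
})

test_that("run comparison is zero on identical inputs and antisymmetric", {
  a <- cycle_summary(mk_series())
  b <- cycle_summary(mk_series(f = function(t) 0.8 * sin(2 * pi * t)))
  expect_true(all(compare_runs(a, a)[, 2:4] == 0))
  expect_true(all(compare_runs(a, a)[, 5:7] == 1))
  ab <- compare_runs(a, b); ba <- compare_runs(b, a)
  expect_equal(ab$d_peak_wss, -ba$d_peak_wss)
  expect_equal(ab$r_peak_velocity, 1 / ba$r_peak_velocity)
  bad <- b; bad$section <- c("S1", "S9")
  expect_error(compare_runs(a, bad), "section")
})

test_that("Womersley oracle: no-slip, quasi-steady limit, annular effect", {
  R <- 0.01; rho <- 1050; eta <- 22e-3; G <- 50
  expect_equal(womersley_solution(R, rho, eta, G, 2 * pi / 0.8, R, 0.3), 0)
  om_lo <- eta / (rho * R^2) * 1e-4          # alpha = 0.01
  u0 <- womersley_solution(R, rho, eta, G, om_lo, 0,
                           t = 2 * pi / om_lo)        # cos(omega t) = 1
  expect_equal(u0, G * R^2 / (4 * eta), tolerance = 1e-3)
  # alpha = 10: centreline amplitude below quasi-steady value
  om10 <- (10 / R)^2 * eta / rho
  tt <- seq(0, 2 * pi / om10, length.out = 400)
  amp <- max(abs(womersley_solution(R, rho, eta, G, om10, rep(0, 400), tt)))
  expect_lt(amp, G * R^2 / (4 * eta))
})

test_that("complex Bessel evaluation matches an independent quadrature", {
  # J_n(z) = (1/pi) Int_0^pi cos(n s - z sin s) ds, valid for complex z
  for (z in list(2 + 1i, 10 - 6i, complex(modulus = 19.4,
                                          argument = 3 * pi / 4))) {
    for (nu in 0:1) {
      quad <- integrate(function(s) Re(cos(nu * s - z * sin(s))), 0, pi,
                        rel.tol = 1e-10)$value / pi +
        1i * integrate(function(s) Im(cos(nu * s - z * sin(s))), 0, pi,
                       rel.tol = 1e-10)$value / pi
      expect_equal(hemofsi:::besselJ_complex(z, nu), quad,
                   tolerance = 1e-7)
    }
  }
})

test_that("Moens-Korteweg speed: value and scaling", {
  expect_equal(moens_korteweg_speed(5e6, 0.002, 1050, 0.010), 21.8,
               tolerance = 1e-2)
  expect_equal(moens_korteweg_speed(4 * 5e6, 0.002, 1050, 0.010),
               2 * moens_korteweg_speed(5e6, 0.002, 1050, 0.010))
})
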