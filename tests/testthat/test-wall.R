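wp <- wall_params()   # E = 5 MPa, h = 2 mm, nu = 0.499, R = 10 mm

test_that("ring stiffness matches the plane-strain closed form", {
  expect_equal(ring_stiffness(wp), 1.3316e8, tolerance = 1e-4)
  wp0 <- wall_params(poisson_ratio = 0)
  expect_equal(ring_stiffness(wp0),
               wp0$youngs_modulus * wp0$thickness / wp0$reference_radius^2)
  wp2 <- wall_params(youngs_modulus = 2 * wp$youngs_modulus)
  expect_equal(ring_stiffness(wp2), 2 * ring_stiffness(wp))
  expect_error(wall_params(poisson_ratio = 0.5), "poisson")
})

test_that("static displacement is p/kappa and linear in pressure", {
  expect_equal(static_displacement(wp, 0), 0)
  expect_equal(static_displacement(wp, 1000), 7.51e-6, tolerance = 1e-3)
  wp_half <- wall_params(youngs_modulus = wp$youngs_modulus / 2)
  expect_equal(static_displacement(wp_half, 1000),
               2 * static_displacement(wp, 1000))
})

test_that("zero pressure keeps the wall at equilibrium", {
  st <- wall_state(20)
  for (i in 1:10) st <- advance_wall(st, 0, wp, 1e-4)
  expect_identical(st$d, numeric(20))
  expect_equal(st$time, 1e-3)
})

test_that("a held static pressure converges to the p/kappa equilibrium", {
  wpd <- wall_params(damping = 3e4)   # near-critical, to settle fast
  st <- wall_state(21)
  for (i in 1:4000) st <- advance_wall(st, 1000, wpd, 2e-5)
  d_exp <- static_displacement(wpd, 1000)
  expect_equal(st$d[11], d_exp, tolerance = 1e-4)
  expect_identical(st$d[c(1, 21)], c(0, 0))   # clamped ends
})

test_that("free-ring oscillation shows the analytic natural frequency", {
  om_n <- sqrt(ring_stiffness(wp) / (wp$rho_wall * wp$thickness))
  expect_equal(om_n, 7.71e3, tolerance = 1e-3)
  dt <- 2 * pi / om_n / 200
  st <- wall_state(3)
  st$d[2] <- 1e-6                       # displacement impulse
  n <- 2000
  trace <- numeric(n)
  for (i in 1:n) {
    st <- advance_wall(st, 0, wp, dt)
    trace[i] <- st$d[2]
  }
  # period from linearly interpolated zero crossings (finer than any
  # FFT bin at this record length); FFT peak confirms the mode is pure
  sgn <- sign(trace)
  idx <- which(sgn[-1] * sgn[-n] < 0)
  tcross <- idx + trace[idx] / (trace[idx] - trace[idx + 1])
  period_meas <- 2 * mean(diff(tcross)) * dt
  expect_equal(2 * pi / period_meas, om_n, tolerance = 0.01)
  sp <- Mod(stats::fft(trace))[2:(n / 2)]
  expect_gt(max(sp) / sum(sp), 0.5)
})

test_that("undamped ring conserves energy within 1% over 100 steps", {
  om_n <- sqrt(ring_stiffness(wp) / (wp$rho_wall * wp$thickness))
  dt <- 2 * pi / om_n / 50
  st <- wall_state(3); st$d[2] <- 1e-6
  kap <- ring_stiffness(wp); m <- wp$rho_wall * wp$thickness
  e0 <- 0.5 * kap * st$d[2]^2
  for (i in 1:100) st <- advance_wall(st, 0, wp, dt)
  e1 <- 0.5 * m * st$v[2]^2 + 0.5 * kap * st$d[2]^2
  expect_equal(e1, e0, tolerance = 0.01)
})

test_that("response is linear: scaled forcing gives scaled displacement", {
  run_wall <- function(p) {
    st <- wall_state(5)
    for (i in 1:200) st <- advance_wall(st, p * sin(i / 20), wp, 1e-5)
    st$d[3]
  }
  expect_equal(run_wall(500), 5 * run_wall(100), tolerance = 1e-10)
})

test_that("rigid mode returns a zero state and the displacement bound trips", {
  wpr <- wall_params(rigid = TRUE)
  st <- wall_state(4); st$d[2] <- 1e-5
  st2 <- advance_wall(st, 1e5, wpr, 1e-3)
  expect_identical(st2$d, numeric(4))
  expect_error(advance_wall(wall_state(4), 1e12, wp, 1),
               "half the radius")
})

test_that("thin-shell reduction error against the thick-walled Lame solution is bounded", {
  # inner-radius displacement of a pressurised thick cylinder in plane
  # strain, h/R = 0.2, vs the ring model
  E <- wp$youngs_modulus; nu <- wp$poisson_ratio
  a <- wp$reference_radius; b <- a + wp$thickness; p <- 1000
  # Lame plane strain via E' = E/(1-nu^2), nu' = nu/(1-nu)
  Ep <- E / (1 - nu^2); nup <- nu / (1 - nu)
  u_lame <- p * a / Ep * ((1 - nup) * a^2 + (1 + nup) * b^2) / (b^2 - a^2)
  # ring stiffness evaluated at the shell mid-surface radius is within
  # 12% of the exact thick-wall answer at h/R = 0.2 ...
  kap_mid <- E * wp$thickness /
    ((1 - nu^2) * (a + wp$thickness / 2)^2)
  expect_lt(abs((p / kap_mid) / u_lame - 1), 0.12)
  # ... while the inner-radius convention used by the solver (the
  # documented stiffness definition) is stiffer; bound its error too
  expect_lt(abs(static_displacement(wp, p) / u_lame - 1), 0.30)
})
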