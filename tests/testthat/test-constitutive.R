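rp <- rheology_params()

test_that("Carreau-Yasuda limits and pointwise value match the closed form", {
  expect_equal(carreau_yasuda_viscosity(0, rp), rp$eta_0)
  expect_equal(carreau_yasuda_viscosity(1e12, rp), rp$eta_inf,
               tolerance = 1e-3)
  # hand-computed: eta_inf + (eta_0-eta_inf) * 2^((n-1)/a) at gamma = 1/lambda
  expect_equal(carreau_yasuda_viscosity(1 / rp$lambda_relax, rp),
               1.249e-2, tolerance = 1e-3)
  expect_error(carreau_yasuda_viscosity(-1, rp), "non-negative")
})

test_that("viscosity is monotone non-increasing and bounded in (eta_inf, eta_0]", {
  g <- 10^seq(-3, 6, length.out = 200)
  eta <- carreau_yasuda_viscosity(g, rp)
  expect_true(all(diff(eta) <= 0))
  expect_true(all(eta > rp$eta_inf & eta <= rp$eta_0))
})

test_that("n = 1 degenerates to a Newtonian fluid of viscosity eta_0", {
  rp1 <- rheology_params(n_exp = 1)
  g <- c(0, 1, 100, 1e5)
  expect_equal(carreau_yasuda_viscosity(g, rp1), rep(rp1$eta_0, 4))
})

test_that("shear-rate magnitude reproduces closed-form tensor contractions", {
  expect_equal(shear_rate_magnitude(), 0)
  expect_equal(shear_rate_magnitude(duz_dr = -7), 7)   # pure axial shear
  # Poiseuille u_z = U(1 - r^2/R^2): du/dr at wall = -2U/R
  U <- 0.3; R <- 0.01
  expect_equal(shear_rate_magnitude(duz_dr = -2 * U / R), 2 * U / R)
  # incompressible biaxial: duz_dz = e, dur_dr = -e/2, hoop = -e/2
  e <- 3
  expect_equal(shear_rate_magnitude(duz_dz = e, dur_dr = -e/2, hoop = -e/2),
               sqrt(2 * (e^2 + e^2 / 2)))
  expect_error(shear_rate_magnitude(duz_dz = Inf), "finite")
})

test_that("shear-rate magnitude agrees with finite differences of an analytic field", {
  # u_z = sin(a z) cos(b r), u_r = r z^2 (axisymmetric, smooth)
  a <- 3; b <- 40
  uz <- function(z, r) sin(a * z) * cos(b * r)
  ur <- function(z, r) r * z^2
  z0 <- 0.07; r0 <- 0.004; h <- 1e-6
  g_fd <- shear_rate_magnitude(
    duz_dz = (uz(z0 + h, r0) - uz(z0 - h, r0)) / (2 * h),
    dur_dr = (ur(z0, r0 + h) - ur(z0, r0 - h)) / (2 * h),
    hoop = ur(z0, r0) / r0,
    duz_dr = (uz(z0, r0 + h) - uz(z0, r0 - h)) / (2 * h),
    dur_dz = (ur(z0 + h, r0) - ur(z0 - h, r0)) / (2 * h))
  g_exact <- shear_rate_magnitude(
    duz_dz = a * cos(a * z0) * cos(b * r0),
    dur_dr = z0^2, hoop = z0^2,
    duz_dr = -b * sin(a * z0) * sin(b * r0),
    dur_dz = 2 * r0 * z0)
  expect_equal(g_fd, g_exact, tolerance = 1e-6)
})

test_that("Kozeny-Carman permeability matches brute-force evaluation", {
  expect_equal(kozeny_carman_permeability(8e-6, 0.5), 1.7778e-13,
               tolerance = 1e-4)
  for (d in c(2e-6, 8e-6, 5e-5)) for (phi in c(0.1, 0.5, 0.9)) {
    expect_identical(kozeny_carman_permeability(d, phi),
                     d^2 * phi^3 / (180 * (1 - phi)^2))
    expect_equal(kozeny_carman_permeability(2 * d, phi),
                 4 * kozeny_carman_permeability(d, phi))
  }
  expect_lt(kozeny_carman_permeability(8e-6, 1e-8), 1e-30)
  expect_error(kozeny_carman_permeability(8e-6, 1.2), "phi")
  expect_error(kozeny_carman_permeability(-1e-6, 0.5), "d must")
})

test_that("Brinkman sink coefficient: value, Darcy identity, linearity", {
  k <- kozeny_carman_permeability(8e-6, 0.5)
  expect_equal(brinkman_sink_coefficient(0.5, 2.2e-3, k), 3.094e9,
               tolerance = 1e-3)
  expect_equal(brinkman_sink_coefficient(1, 2.2e-3, k), 2.2e-3 / k)
  expect_equal(brinkman_sink_coefficient(0.5, 3 * 2.2e-3, k),
               3 * brinkman_sink_coefficient(0.5, 2.2e-3, k))
  expect_error(brinkman_sink_coefficient(0.5, 2.2e-3, 0), "permeability")
})

test_that("parameter containers enforce their invariants", {
  expect_error(rheology_params(eta_0 = 1e-3), "eta_0 > eta_inf")
  expect_error(rheology_params(n_exp = 0), "n_exp")
  expect_error(porous_params(porosity = 0), "porosity")
  expect_error(porous_params(area_expansion = 0.5), "area_expansion")
  expect_equal(porous_params()$permeability,
               kozeny_carman_permeability(8e-6, 0.5))
  expect_equal(porous_params(permeability = 1e-10)$permeability, 1e-10)
})
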