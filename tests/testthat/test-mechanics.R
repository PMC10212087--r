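test_that("spring constant follows the Euler-Bernoulli tip-load relation", {
  # 3 * E I / L^3 with I = w t^3 / 12, evaluated by hand for the printed
  # beam geometry and a 4 GPa material modulus
  expect_equal(cantilever_spring_constant(cantilever_preset()),
               0.08239746, tolerance = 1e-6)
  # cubic thickness law
  k1 <- cantilever_spring_constant(cantilever_spec(thickness_m = 15e-6))
  k2 <- cantilever_spring_constant(cantilever_spec(thickness_m = 30e-6))
  expect_equal(k2 / k1, 8)
  # explicit spring constant overrides geometry
  expect_equal(cantilever_spring_constant(
    cantilever_spec(thickness_m = 1, spring_constant = 0.5)), 0.5)
  expect_error(cantilever_spring_constant(
    cantilever_spec(material_modulus_pa = NULL)), "spring_constant")
})

test_that("plate-contact force matches the closed form and its symmetries", {
  expect_equal(hertz_force(600, 0.5, 212.5e-6, 0), 0)
  # hand-evaluated closed form
  expect_equal(hertz_force(600, 0.5, 212.5e-6, 40e-6), 1.390763e-6,
               tolerance = 1e-6)
  # linear in E
  expect_equal(hertz_force(1200, 0.5, 212.5e-6, 40e-6),
               2 * hertz_force(600, 0.5, 212.5e-6, 40e-6))
  expect_error(hertz_force(600, 0.5, 212.5e-6, -1e-6), ">= 0")
})

test_that("plate-contact force is monotone in modulus, radius and compression", {
  base <- hertz_force(500, 0.5, 200e-6, 30e-6)
  for (f in list(function() hertz_force(600, 0.5, 200e-6, 30e-6),
                 function() hertz_force(500, 0.5, 250e-6, 30e-6),
                 function() hertz_force(500, 0.5, 200e-6, 40e-6)))
    expect_gt(f(), base)
})

test_that("equilibrium solver handles the degenerate contact cases", {
  cant <- cantilever_preset()
  sph <- spheroid_spec(425, 600)
  # tips wider apart than the sphere: no contact
  eq <- solve_equilibrium_step(430, cant, sph)
  expect_equal(unlist(eq), c(tip_deflection_um = 0, contact_force_n = 0,
                             compression_um = 0))
  # zero modulus: no restoring force, full commanded compression
  eq0 <- solve_equilibrium_step(380, cant, spheroid_spec(425, 0))
  expect_equal(eq0$tip_deflection_um, 0)
  expect_equal(eq0$contact_force_n, 0)
  expect_equal(eq0$compression_um, 45)
})

test_that("equilibrium deflection agrees with a dense grid scan of the residual", {
  cant <- cantilever_spec(spring_constant = 0.08)
  sph <- spheroid_spec(425, 600, 0.5)
  eq <- solve_equilibrium_step(380, cant, sph)
  # brute-force oracle: scan 1e6 candidate deflections for the smallest
  # force residual
  d_grid <- seq(0, (425 - 380) / 2, length.out = 1e6) * 1e-6
  delta <- pmax(0, 425e-6 - (380e-6 + 2 * d_grid))
  resid <- abs(0.08 * d_grid -
               (4 / 3) * 600 / (1 - 0.25) * sqrt(212.5e-6) * (delta / 2)^1.5)
  d_best <- d_grid[which.min(resid)] * 1e6
  expect_lt(abs(eq$tip_deflection_um - d_best), 1e-3)
  # residual of the returned solution is at the stated tolerance
  F_back <- hertz_force(600, 0.5, 212.5e-6, eq$compression_um * 1e-6)
  expect_lt(abs(0.08 * eq$tip_deflection_um * 1e-6 - F_back), 1e-12)
})

test_that("deflection-to-force conversion is k times the mean tip magnitude", {
  defl <- list(upper_um = c(0, -10), lower_um = c(0, 10))
  expect_equal(force_from_deflection(defl, 0.08), c(0, 0.8e-6))
  # inward (negative-magnitude) deflections are clipped with a warning
  expect_warning(
    f <- force_from_deflection(list(upper_um = 0.5, lower_um = 10), 0.08),
    "clipped")
  expect_equal(f, 0.08 * 10 / 2 * 1e-6)
})

test_that("compression series thresholds at the diameter", {
  expect_error(compression_series(c(430, 428), 425), "no contact")
  cs <- compression_series(c(430, 415), 425)
  expect_equal(cs$delta_um, c(0, 10))
  expect_identical(cs$contact_step, 2L)
})

test_that("modulus fit is exact on noiseless curves and matches the grid oracle", {
  set.seed(11)
  delta <- seq(5, 60, by = 5)
  g <- (4 / 3) / (1 - 0.25) * sqrt(212.5e-6) * (delta * 1e-6 / 2)^1.5
  # noiseless self-consistency
  curve <- force_displacement_curve(delta, 500 * g, 212.5, 0.5)
  expect_equal(fit_modulus(curve)$youngs_modulus_pa, 500, tolerance = 1e-9)
  # noisy curves: closed form within half a grid step of the exhaustive scan
  for (i in 1:20) {
    E_true <- runif(1, 50, 1500)
    F <- E_true * g * (1 + rnorm(length(g), 0, 0.05))
    curve <- force_displacement_curve(delta, F, 212.5, 0.5)
    E_fit <- fit_modulus(curve)$youngs_modulus_pa
    E_grid <- suppressWarnings(
      modulus_oracle(curve, seq(1, 2000, by = 1))$youngs_modulus_pa)
    expect_lte(abs(E_fit - E_grid), 0.5)
  }
})

test_that("single-point grid oracle solves the one-parameter problem exactly", {
  g <- (4 / 3) / (1 - 0.25) * sqrt(212.5e-6) * (20e-6 / 2)^1.5
  curve <- force_displacement_curve(20, 400 * g, 212.5, 0.5)
  est <- suppressWarnings(modulus_oracle(curve, seq(399.5, 400.5, by = 0.001)))
  expect_equal(est$youngs_modulus_pa, 400, tolerance = 1e-3)
})

test_that("all-zero forces give modulus 0 with a warning; short curves error", {
  expect_warning(
    est <- fit_modulus(force_displacement_curve(c(5, 10), c(0, 0), 212.5, 0.5)),
    "zero")
  expect_equal(est$youngs_modulus_pa, 0)
  expect_error(fit_modulus(force_displacement_curve(c(0, 10), c(0, 1e-6),
                                                    212.5, 0.5)),
               "at least 2")
})

test_that("model force ratio equals the modulus ratio at any indentation", {
  expect_equal(force_ratio(500, 500), 1)
  expect_equal(force_ratio(680, 260), 680 / 260)
  for (d in c(5, 20, 50))
    expect_equal(force_ratio(680, 260, delta_um = d), 680 / 260)
})
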