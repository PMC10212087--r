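test_that("rendering stamps the template exactly at integer positions", {
  tpl <- default_tip_template()
  spec <- image_spec(60, 120, 2)
  fr <- render_tip_frame(rbind(c(30, 40), c(30, 100)), tpl, spec, noise_sd = 0)
  a <- tpl$anchor
  patch <- fr[(40 - a[1] + 1):(40 - a[1] + nrow(tpl$raster)),
              (30 - a[2] + 1):(30 - a[2] + ncol(tpl$raster))]
  expect_equal(patch, tpl$raster)
  # background untouched
  expect_equal(fr[1, 1], 0)
})

test_that("half-pixel placement equals the average of the two integer placements", {
  tpl <- default_tip_template()
  spec <- image_spec(60, 120, 2)
  pos <- function(y) rbind(c(30, y), c(30, 100))
  f40 <- render_tip_frame(pos(40), tpl, spec, 0)
  f41 <- render_tip_frame(pos(41), tpl, spec, 0)
  fh <- render_tip_frame(pos(40.5), tpl, spec, 0)
  # bilinear weights at a pure half-pixel shift are (1/2, 1/2)
  expect_equal(fh, (f40 + f41) / 2)
})

test_that("rendering is deterministic given the seed and validates geometry", {
  tpl <- default_tip_template()
  spec <- image_spec(60, 120, 2)
  pos <- rbind(c(30, 40), c(30, 100))
  expect_identical(render_tip_frame(pos, tpl, spec, 0.05, seed = 9),
                   render_tip_frame(pos, tpl, spec, 0.05, seed = 9))
  # overlapping stamps rejected
  expect_error(render_tip_frame(rbind(c(30, 40), c(30, 50)), tpl, spec, 0),
               "overlap")
  # stamps must stay inside the frame
  expect_error(render_tip_frame(rbind(c(30, 5), c(30, 100)), tpl, spec, 0),
               "field of view")
})

test_that("a zero-modulus spheroid leaves loaded and reference runs identical", {
  prof <- build_actuation_profile(2, 10, 2)
  sim <- simulate_compression_experiment(
    prof, cantilever_preset(), spheroid_spec(100, 0),
    spec = image_spec(60, 120, 2), noise_sd = 0, seed = 1,
    initial_gap_um = 30)
  expect_identical(sim$reference, sim$loaded)
})

test_that("reference-run tips advance by exactly the per-step displacement", {
  sim <- mech_run("day5", 1, noise_sd = 0.02)$sim
  # ground truth of the no-noise kinematics: commanded separations
  steps_diff <- diff(sim$truth$commanded_separation_um) / 2
  expect_equal(unique(round(abs(steps_diff), 9)), 4.9)
  # and the rendered (noise-free) truth positions move accordingly
  y_up <- vapply(sim$truth$reference_positions_px, function(p) p[1, 2],
                 numeric(1))
  expect_equal(diff(y_up) * sim$image_spec$pixel_pitch_um,
               rep(4.9, length(y_up) - 1))
})

test_that("simulation is bit-reproducible and respects the force balance", {
  cfg <- age_config("day5")
  s1 <- mech_run("day5", 1)$sim
  s2 <- suppressWarnings(run_compression_analysis(cfg, 1))$sim
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$loaded, s2$loaded)
  # truth satisfies k d = F_hertz(delta) at every step
  k <- cfg$spring_constant
  sph <- spheroid_preset("day5")
  F_check <- vapply(s1$truth$compression_um, function(d)
    hertz_force(sph$youngs_modulus_pa, sph$poisson_ratio,
                sph$diameter_um / 2 * 1e-6, d * 1e-6), numeric(1))
  expect_true(all(abs(k * s1$truth$deflection_um * 1e-6 - F_check) < 1e-12))
  # deflection non-decreasing after first contact
  d <- s1$truth$deflection_um
  first <- which(d > 0)[1]
  expect_true(all(diff(d[first:length(d)]) >= -1e-12))
})

test_that("the stiffer preset bends the cantilevers more at every post-contact step", {
  s5 <- mech_run("day5", 1)$sim
  s20 <- mech_run("day20", 1)$sim
  # compare at equal compression by interpolating deflection vs compression
  c5 <- s5$truth$compression_um; d5 <- s5$truth$deflection_um
  c20 <- s20$truth$compression_um; d20 <- s20$truth$deflection_um
  shared <- seq(5, min(max(c5), max(c20)), length.out = 20)
  expect_true(all(approx(c20, d20, shared)$y > approx(c5, d5, shared)$y))
})

test_that("TIFF sequences round-trip through disk", {
  tpl <- default_tip_template()
  spec <- image_spec(40, 80, 2)
  frames <- lapply(1:3, function(i)
    render_tip_frame(rbind(c(20, 25), c(20, 60 + i)), tpl, spec, 0))
  dir <- withr::local_tempdir()
  write_image_sequence(frames, dir)
  back <- read_image_sequence(dir)
  expect_length(back, 3)
  # 16-bit quantisation error only
  expect_lt(max(abs(back[[2]] - frames[[2]])), 1 / 65535)
})
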