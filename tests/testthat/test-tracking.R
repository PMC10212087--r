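test_that("matching finds an exact embed with score 1", {
  tpl <- default_tip_template()
  spec <- image_spec(80, 100, 2)
  fr <- render_tip_frame(rbind(c(60, 40)), tpl, spec, 0)
  m <- match_template(fr, tpl)
  expect_equal(unname(m$pos), c(60, 40))
  expect_equal(m$score, 1, tolerance = 1e-12)
})

test_that("score ties break to the smallest row, then column", {
  tpl <- tip_template(matrix(c(0, 1, 1, 0), 2, 2), anchor = c(1, 1))
  fr <- matrix(0, 10, 10)
  fr[7:8, 3:4] <- matrix(c(0, 1, 1, 0), 2)  # embed at row 7
  fr[2:3, 6:7] <- matrix(c(0, 1, 1, 0), 2)  # identical embed at row 2
  m <- match_template(fr, tpl)
  expect_equal(unname(m$pos["y"]), 2)
})

test_that("NCC peak agrees with an exhaustive SSD matcher under noise", {
  tpl <- default_tip_template()
  spec <- image_spec(60, 80, 2)
  set.seed(5)
  for (i in 1:5) {
    pos <- c(sample(25:35, 1), sample(30:50, 1))
    fr <- render_tip_frame(rbind(pos), tpl, spec, noise_sd = 0.05,
                           seed = 100 + i)
    m <- match_template(fr, tpl)
    # brute-force oracle: minimise the sum of squared differences over
    # every anchor placement
    tr <- tpl$raster; a <- tpl$anchor
    best <- c(NA, NA); best_ssd <- Inf
    for (r in a[1]:(nrow(fr) - (nrow(tr) - a[1]))) {
      for (cc in a[2]:(ncol(fr) - (ncol(tr) - a[2]))) {
        p <- fr[(r - a[1] + 1):(r - a[1] + nrow(tr)),
                (cc - a[2] + 1):(cc - a[2] + ncol(tr))]
        ssd <- sum((p - tr)^2)
        if (ssd < best_ssd) { best_ssd <- ssd; best <- c(cc, r) }
      }
    }
    expect_lte(max(abs(unname(m$pos) - best)), 1)
  }
})

test_that("constant windows raise an undefined-correlation error", {
  tpl <- default_tip_template()
  fr <- matrix(0.5, 60, 60)
  expect_error(match_template(fr, tpl), "constant")
})

test_that("parabolic refinement handles symmetric, flat and border peaks", {
  s <- matrix(0, 5, 5)
  s[3, 3] <- 1; s[2, 3] <- 0.5; s[4, 3] <- 0.5; s[3, 2] <- 0.5; s[3, 4] <- 0.5
  expect_equal(unname(refine_subpixel(s, c(3, 3))), c(3, 3))
  flat <- matrix(1, 3, 3)
  expect_equal(unname(refine_subpixel(flat, c(2, 2))), c(2, 2))
  expect_warning(out <- refine_subpixel(s, c(1, 3)), "border")
  expect_equal(unname(out), c(1, 3))
})

test_that("sub-pixel offsets are recovered from fractionally shifted frames", {
  tpl <- default_tip_template()
  spec <- image_spec(60, 80, 2)
  fr <- render_tip_frame(rbind(c(30, 40.3)), tpl, spec, 0)
  m <- match_template(fr, tpl)
  pk <- which(m$surface == m$score, arr.ind = TRUE)[1, ]
  sub <- refine_subpixel(m$surface, pk)
  y <- m$surface_rows[1] + sub[1] - 1
  expect_equal(unname(y), 40.3, tolerance = 0.1)
})

test_that("noiseless tracking reproduces ground truth to < 0.05 px RMS", {
  cfg <- age_config("day5")
  cfg$noise_sd <- 0
  res <- suppressWarnings(run_compression_analysis(cfg, 3))
  err_ref <- rms_tracking_error(res$trajectories$reference,
                                truth_positions(res$sim, "reference"))
  err_load <- rms_tracking_error(res$trajectories$loaded,
                                 truth_positions(res$sim, "loaded"))
  expect_lt(err_ref, 0.05)
  expect_lt(err_load, 0.05)
  # deflections match the equilibrium ground truth to < 0.1 um
  expect_lt(max(abs(-res$deflections$upper_um - res$sim$truth$deflection_um)),
            0.1)
})

test_that("tracking at 5% pixel noise stays below 0.3 px RMS", {
  res <- mech_run("day5", 4, noise_sd = 0.05)
  err <- rms_tracking_error(res$trajectories$reference,
                            truth_positions(res$sim, "reference"))
  expect_lt(err, 0.3)
})

test_that("tracking is exactly equivariant under integer frame shifts", {
  tpl <- default_tip_template()
  spec <- image_spec(60, 120, 2)
  mkframe <- function(y1, y2) render_tip_frame(rbind(c(30, y1), c(30, y2)),
                                               tpl, spec, 0)
  frames <- list(mkframe(30, 90), mkframe(32.4, 88.1), mkframe(34.8, 85.7))
  shift <- function(m, dy, dx) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <-
      m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  shifted <- lapply(frames, shift, dy = 7, dx = 4)
  init <- rbind(c(30, 30), c(30, 90))
  t0 <- track_tips(frames, tpl, init)
  t1 <- track_tips(shifted, tpl, init + rep(c(4, 7), each = 2))
  expect_equal(t1$x_px, t0$x_px + 4)
  expect_equal(t1$y_px, t0$y_px + 7)
})

test_that("a sequence of identical frames yields a constant trajectory", {
  tpl <- default_tip_template()
  spec <- image_spec(60, 120, 2)
  fr <- render_tip_frame(rbind(c(30, 40), c(30, 90)), tpl, spec, 0)
  traj <- track_tips(list(fr, fr, fr), tpl, rbind(c(30, 40), c(30, 90)))
  expect_equal(unique(traj$y_px[traj$tip == "upper"]), 40)
  expect_equal(unique(traj$y_px[traj$tip == "lower"]), 90)
})

test_that("an undersized search radius loses the track loudly", {
  tpl <- default_tip_template()
  spec <- image_spec(60, 160, 2)
  frames <- lapply(0:6, function(i)
    render_tip_frame(rbind(c(30, 40 + 4 * i), c(30, 140 - 4 * i)), tpl,
                     spec, 0))
  expect_error(
    track_tips(frames, tpl, rbind(c(30, 40), c(30, 140)), search_radius = 2),
    "tracking lost|constant")
})

test_that("deflection computation is antisymmetric and validates steps", {
  res <- mech_run("day5", 1)
  lod <- res$trajectories$loaded; ref <- res$trajectories$reference
  d1 <- compute_deflections(lod, ref, 2)
  d2 <- compute_deflections(ref, lod, 2)
  expect_equal(d1$upper_um, -d2$upper_um)
  expect_equal(d1$lower_um, -d2$lower_um)
  # identical runs: zero deflection everywhere
  d0 <- compute_deflections(ref, ref, 2)
  expect_true(all(d0$upper_um == 0) && all(d0$lower_um == 0))
  short <- ref[ref$step < max(ref$step), ]
  class(short) <- class(ref)
  expect_error(compute_deflections(lod, short, 2), "different step counts")
})
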