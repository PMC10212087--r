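test_that("region presets validate their statistics", {
  expect_error(tem_region_preset("inner", 100, 50, 40, 20, 1.0), "< 1")
  expect_error(tem_region_preset("inner", 100, 50, 120, 20, 0.1),
               "below mean cell area")
  expect_error(tem_region_preset("inner", -5, 50, 40, 20, 0.1), "> 0")
})

test_that("identical seeds give identical polygon sets", {
  t1 <- small_tessellation(seed = 3)
  t2 <- sample_cell_tessellation(160, 60, small_tem_preset(), seed = 3)
  expect_identical(t1, t2)
  t3 <- small_tessellation(seed = 4)
  expect_false(identical(lapply(t1, `[[`, "cell"), lapply(t3, `[[`, "cell")))
})

test_that("every nucleus lies strictly inside its cell", {
  tess <- small_tessellation(seed = 2)
  for (cl in tess) {
    expect_true(all(spheromech:::points_in_polygon(
      cl$nucleus[, 1], cl$nucleus[, 2], cl$cell)))
  }
})

test_that("zero target density tiles the strip almost completely", {
  tess <- small_tessellation(seed = 1, rho_inner = 0, rho_outer = 0,
                             style = "uniform")
  panel <- strip_as_panel(tess)
  dens <- intercellular_space_density(panel, resolution = 2)
  expect_lt(dens, 0.5)  # percent uncovered at render resolution
})

test_that("shrink calibration hits the target density in every region", {
  # realised region-wise uncovered fraction within +/- 1 percentage
  # point of the preset across seeds
  for (s in 1:10) {
    tess <- small_tessellation(seed = s)
    expect_lt(abs(region_uncovered_exact(tess, "inner") - 0.10), 0.01)
    expect_lt(abs(region_uncovered_exact(tess, "outer") - 0.14), 0.01)
  }
})

test_that("realised cell areas reproduce the preset law at pooled N >= 200", {
  strips <- tem_strips("day5")
  cells <- do.call(rbind, lapply(strips, `[[`, "cells"))
  cells <- cells[cells$complete & cells$region == "inner", ]
  expect_gte(nrow(cells), 200)
  sem_mean <- 53 / sqrt(nrow(cells))
  sem_sd <- 53 / sqrt(2 * nrow(cells))
  expect_lt(abs(mean(cells$cell_area_um2) - 123), 3 * sem_mean)
  expect_lt(abs(sd(cells$cell_area_um2) - 53), 3 * sem_sd)
})

test_that("panels tile the strip with overlap and consistent clip flags", {
  tess <- small_tessellation(seed = 5)
  panels <- render_tem_panels(tess, panel_width_um = 50, overlap_frac = 0.1,
                              render = FALSE)
  expect_gte(length(panels), 3)
  # first and last panels contain the spheroid edge
  edge <- vapply(panels, `[[`, logical(1), "contains_spheroid_edge")
  expect_true(edge[1] && edge[length(edge)] && !any(edge[2:(length(edge) - 1)]))
  # interval overlap equals the stated fraction
  expect_equal(panels[[1]]$x_end_um - panels[[2]]$x_start_um, 0.1 * 50)
  # a cell straddling a boundary is flagged clipped in both panels
  b <- panels[[2]]$x_start_um
  straddler <- Filter(function(cl) min(cl$cell[, 1]) < b &
                                   max(cl$cell[, 1]) > b, tess)[[1]]
  for (p in panels[1:2]) {
    entry <- Filter(function(x) x$cell_id == straddler$cell_id, p$cells)
    expect_length(entry, 1)
    expect_true(entry[[1]]$clipped)
  }
})

test_that("a single panel spanning the strip carries the whole tessellation", {
  tess <- small_tessellation(seed = 6)
  panel <- strip_as_panel(tess)
  expect_equal(length(panel$cells), length(tess))
  expect_false(any(vapply(panel$cells, `[[`, logical(1), "clipped")))
})

test_that("rasterised panel density matches the exact polygon geometry", {
  tess <- small_tessellation(seed = 7)
  panels <- render_tem_panels(tess, panel_width_um = 50, render = FALSE)
  for (p in panels[2:3]) {
    exact <- space_density_exact(p)
    raster <- intercellular_space_density(p, resolution = 2)
    expect_lt(abs(raster - exact), 1)  # < 1 percentage point at 2 px/um
  }
})

test_that("panel rasters shade gaps, cells and nuclei distinctly", {
  tess <- small_tessellation(seed = 8)
  p <- render_tem_panels(tess, panel_width_um = 50)[[2]]
  expect_setequal(unique(as.vector(p$raster)), c(0.88, 0.55, 0.25))
  # uncovered pixel fraction consistent with the density measurement
  dens <- intercellular_space_density(p, resolution = p$resolution)
  expect_equal(100 * mean(p$raster == 0.88), dens)
})
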