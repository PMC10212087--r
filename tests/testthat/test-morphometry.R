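fake_panel <- function(x0 = 0, x1 = 10, h = 10, cells = list()) {
  structure(list(panel_id = 1L, x_start_um = x0, x_end_um = x1,
                 contains_spheroid_edge = FALSE, strip_height_um = h,
                 resolution = 2, cells = cells, raster = NULL),
            class = "tem_panel")
}

square <- function(x0, x1, y0, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))

test_that("the complete-cell rule excludes boundary and anucleate cells", {
  panel <- fake_panel(0, 100, 50)
  interior <- list(cell = square(10, 20, 10, 20),
                   nucleus = square(12, 18, 12, 18))
  expect_true(is_complete_cell(interior, panel))
  # touching the panel boundary: omitted
  touching <- list(cell = square(0, 10, 10, 20),
                   nucleus = square(2, 8, 12, 18))
  expect_false(is_complete_cell(touching, panel))
  top <- list(cell = square(10, 20, 40, 50), nucleus = square(12, 18, 42, 48))
  expect_false(is_complete_cell(top, panel))
  # no nucleus visible: omitted
  expect_false(is_complete_cell(list(cell = square(10, 20, 10, 20),
                                     nucleus = NULL), panel))
  # nucleus poking outside its cell: omitted
  expect_false(is_complete_cell(list(cell = square(10, 20, 10, 20),
                                     nucleus = square(15, 25, 12, 18)),
                                panel))
})

test_that("complete-cell filtering matches the generator's clip flags", {
  tess <- small_tessellation(seed = 9)
  panel <- strip_as_panel(tess)
  complete <- vapply(tess, is_complete_cell, logical(1), panel = panel)
  # an independent bounding-box check of the same rule
  L <- attr(tess, "strip_length_um"); H <- attr(tess, "strip_height_um")
  bbox_interior <- vapply(tess, function(cl)
    min(cl$cell[, 1]) > 1e-9 && max(cl$cell[, 1]) < L - 1e-9 &&
    min(cl$cell[, 2]) > 1e-9 && max(cl$cell[, 2]) < H - 1e-9, logical(1))
  expect_identical(complete, complete & bbox_interior)
  expect_gt(sum(complete), 0)
  # filtering never increases N
  expect_lte(sum(complete), length(tess))
})

test_that("region partition assigns the central half as inner, half-open", {
  expect_equal(partition_regions(c(10, 50), c(0, 100)), c("outer", "inner"))
  # boundary centroid belongs to the inner interval
  expect_equal(partition_regions(25, c(0, 100)), "inner")
  expect_equal(partition_regions(75, c(0, 100)), "outer")  # half-open at 75
  expect_error(partition_regions(120, c(0, 100)), "outside")
  # exhaustive and exclusive over a tessellation
  tess <- small_tessellation(seed = 2)
  labels <- partition_regions(vapply(tess, function(cl) cl$centroid[1],
                                     numeric(1)),
                              c(0, attr(tess, "strip_length_um")))
  expect_true(all(labels %in% c("inner", "outer")))
  expect_equal(sum(labels == "inner") + sum(labels == "outer"), length(tess))
})

test_that("density panel selection picks the centre and edge-free flanks", {
  mk <- function(id, x0, x1, edge) structure(
    list(panel_id = id, x_start_um = x0, x_end_um = x1,
         contains_spheroid_edge = edge, strip_height_um = 10,
         cells = list(), raster = NULL), class = "tem_panel")
  panels <- list(mk(1, 0, 20, TRUE), mk(2, 18, 38, FALSE),
                 mk(3, 36, 56, FALSE), mk(4, 54, 74, FALSE),
                 mk(5, 72, 92, TRUE))
  sel <- select_density_panels(panels)
  expect_equal(sel$center$panel_id, 3L)
  expect_equal(vapply(sel$outer, function(p) as.integer(p$panel_id),
                      integer(1)), c(2L, 4L))
  all_edge <- lapply(panels, function(p) { p$contains_spheroid_edge <- TRUE; p })
  expect_error(select_density_panels(all_edge), "no edge-free panel")
  expect_error(select_density_panels(panels[1:2]), "at least 3")
})

test_that("space density is the exact uncovered pixel percentage", {
  # fully tiled panel
  full <- fake_panel(cells = list(list(cell = square(0, 10, 0, 10))))
  expect_equal(intercellular_space_density(full), 0)
  # one square covering exactly half the panel
  half <- fake_panel(cells = list(list(cell = square(0, 5, 0, 10))))
  expect_equal(intercellular_space_density(half), 50)
  # complement identity at any resolution
  tess <- small_tessellation(seed = 3)
  p <- render_tem_panels(tess, panel_width_um = 50, render = FALSE)[[2]]
  for (res in c(1, 2, 4)) {
    polys <- lapply(p$cells, `[[`, "cell")
    nx <- round((p$x_end_um - p$x_start_um) * res)
    ny <- round(p$strip_height_um * res)
    mask <- spheromech:::fill_polygons_mask(polys, p$x_start_um, 0, nx, ny, res)
    covered <- 100 * sum(mask) / length(mask)
    expect_identical(intercellular_space_density(p, resolution = res) + covered,
                     100)
  }
  # empty panel warns and reports 100%
  expect_warning(d <- intercellular_space_density(fake_panel()), "no cells")
  expect_equal(d, 100)
})

test_that("density converges as the raster is refined", {
  tess <- small_tessellation(seed = 4)
  p <- render_tem_panels(tess, panel_width_um = 50, render = FALSE)[[3]]
  d2 <- intercellular_space_density(p, resolution = 2)
  d4 <- intercellular_space_density(p, resolution = 4)
  expect_lt(abs(d4 - d2), 0.2)
})

test_that("group summaries pool correctly and ignore input order", {
  strip <- list(cells = data.frame(
    cell_id = 1:6,
    region = c("inner", "inner", "inner", "outer", "outer", "outer"),
    cell_area_um2 = c(4, 4, 4, 7, 9, 11),
    nucleus_area_um2 = c(1, 1, 1, 2, 3, 4),
    complete = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    inner_density = 5, outer_density = 10)
  s <- summarize_groups(list(day5 = list(strip)))
  inner <- s$areas[s$areas$region == "inner", ]
  expect_equal(inner$cell_mean, 4)
  expect_equal(inner$cell_sd, 0)
  expect_equal(inner$cell_n, 3L)
  outer <- s$areas[s$areas$region == "outer", ]
  expect_equal(outer$cell_n, 2L)  # the incomplete cell is excluded
  # single-spheroid densities report NA SD
  expect_true(is.na(s$density$sd[1]))
  # permuting the cells leaves the summary unchanged
  strip2 <- strip
  strip2$cells <- strip$cells[sample(6), ]
  s2 <- summarize_groups(list(day5 = list(strip2)))
  expect_equal(s$areas, s2$areas)
})
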