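# TEM cross-section morphometry: complete-cell filtering, inner/outer
# region partition, density-panel selection, intercellular space density,
# and the grouped summary statistics.

#' Is a cell complete within a panel?
#'
#' A cell is counted only if its entire outline lies strictly inside the
#' panel bounds (no part cut away by the image edge) and it carries a
#' nucleus whose outline lies fully inside the cell outline. Cells
#' touching the panel boundary are omitted.
#'
#' @param cell A list with `cell` (or `full_cell`) and `nucleus`
#'   (or `full_nucleus`) polygons in strip coordinates.
#' @param panel A `tem_panel` (see [render_tem_panels()]).
#' @return `TRUE` or `FALSE`.
#' @export
is_complete_cell <- function(cell, panel) {
  poly <- cell$full_cell %||% cell$cell
  nuc  <- cell$full_nucleus %||% cell$nucleus
  eps <- 1e-9
  inside <- all(poly[, 1L] > panel$x_start_um + eps) &&
            all(poly[, 1L] < panel$x_end_um - eps) &&
            all(poly[, 2L] > eps) &&
            all(poly[, 2L] < panel$strip_height_um - eps)
  if (!inside || is.null(nuc)) return(FALSE)
  all(points_in_polygon(nuc[, 1L], nuc[, 2L], poly))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition cells into inner and outer regions
#'
#' Labels each cell by its centroid position along the primary axis:
#' `inner` for centroids in the central half of the occupied extent
#' (half-open interval, so a centroid exactly on the 25% boundary is
#' inner), `outer` for the flanking quarters.
#'
#' @param centroids_x Numeric vector of centroid x positions (um).
#' @param extent Length-2 vector `c(x_min, x_max)` of the occupied axis
#'   range.
#' @return Character vector of `"inner"`/`"outer"` labels.
#' @export
partition_regions <- function(centroids_x, extent) {
  abort_if(length(extent) != 2L || extent[2L] <= extent[1L],
           "'extent' must be c(x_min, x_max) with x_min < x_max")
  abort_if(any(centroids_x < extent[1L] - 1e-9 |
               centroids_x > extent[2L] + 1e-9),
           "cell centroid outside the axis extent")
  Lx <- extent[2L] - extent[1L]
  lo <- extent[1L] + 0.25 * Lx
  hi <- extent[1L] + 0.75 * Lx
  ifelse(centroids_x >= lo & centroids_x < hi, "inner", "outer")
}

#' Select the density panels of a strip
#'
#' The panel whose midpoint is closest to the strip midpoint is the
#' "center" panel (ties broken by the lower panel id). On each side, the
#' outermost panel that does not contain any part of the spheroid edge is
#' an "outer" panel (often the second-to-outermost).
#'
#' @param panels List of `tem_panel`s, in axis order.
#' @return List with `center` (one panel) and `outer` (list of two
#'   panels, left then right).
#' @export
select_density_panels <- function(panels) {
  abort_if(length(panels) < 3L, "need at least 3 panels")
  mids <- vapply(panels, function(p) (p$x_start_um + p$x_end_um) / 2, numeric(1))
  edge <- vapply(panels, `[[`, logical(1), "contains_spheroid_edge")
  extent_mid <- (min(vapply(panels, `[[`, numeric(1), "x_start_um")) +
                 max(vapply(panels, `[[`, numeric(1), "x_end_um"))) / 2
  center <- panels[[which.min(abs(mids - extent_mid))]]
  ord <- order(mids)
  left_ok  <- ord[!edge[ord] & mids[ord] < extent_mid]
  right_ok <- rev(ord)[!edge[rev(ord)] & mids[rev(ord)] > extent_mid]
  abort_if(!length(left_ok),  "no edge-free panel on the left side")
  abort_if(!length(right_ok), "no edge-free panel on the right side")
  list(center = center,
       outer = list(panels[[left_ok[1L]]], panels[[right_ok[1L]]]))
}

#' Intercellular space density of a panel
#'
#' Reproduces the space-filling measurement: the (clipped) cell outlines
#' are filled on a raster covering the full panel at the stated
#' resolution, and the density is the percentage of panel pixels not
#' covered by any cell. By construction
#' `density + covered percentage = 100` exactly.
#'
#' @param panel A `tem_panel`.
#' @param cells List of clipped cell polygons (defaults to the panel's
#'   own cells).
#' @param resolution Raster resolution (px/um, default 2).
#' @return Density in percent.
#' @export
intercellular_space_density <- function(panel, cells = panel$cells,
                                        resolution = 2) {
  assert_number(resolution, "resolution", positive = TRUE)
  polys <- lapply(cells, function(cl) if (is.list(cl)) cl$cell else cl)
  if (!length(polys)) {
    warning("no cells in panel: density is 100%", call. = FALSE)
    return(100)
  }
  nx <- round((panel$x_end_um - panel$x_start_um) * resolution)
  ny <- round(panel$strip_height_um * resolution)
  mask <- fill_polygons_mask(polys, panel$x_start_um, 0, nx, ny, resolution)
  100 * (1 - sum(mask) / length(mask))
}

#' Exact polygon-based space density (oracle)
#'
#' The same quantity as [intercellular_space_density()] computed from the
#' polygon areas clipped to the panel, with no rasterisation. Valid when
#' cells do not overlap (true of synthetic tessellations); used as the
#' geometric cross-check for the raster route.
#'
#' @inheritParams intercellular_space_density
#' @return Density in percent.
#' @export
space_density_exact <- function(panel, cells = panel$cells) {
  polys <- lapply(cells, function(cl) if (is.list(cl)) cl$cell else cl)
  area <- (panel$x_end_um - panel$x_start_um) * panel$strip_height_um
  cov <- sum(vapply(polys, function(p) {
    q <- clip_rect(p, panel$x_start_um, panel$x_end_um, 0,
                   panel$strip_height_um)
    if (nrow(q) >= 3L) abs(shoelace_signed(q)) else 0
  }, numeric(1)))
  100 * (1 - cov / area)
}

#' Morphometry of one tessellated strip
#'
#' Applies the measurement protocol to a strip: complete cells are those
#' entirely inside the stitched image with their whole nucleus; regions
#' are assigned by centroid under the inner-50%/outer-25% partition of
#' the strip extent; panel densities are measured on the center panel and
#' the two outermost edge-free panels.
#'
#' @param tess A [sample_cell_tessellation()].
#' @param panel_width_um,overlap_frac,resolution Panel layout and raster
#'   parameters (see [render_tem_panels()]).
#' @return List with `cells` (data frame: `cell_id`, `region`,
#'   `cell_area_um2`, `nucleus_area_um2`, `complete`), `inner_density`,
#'   `outer_density` (percent), and `panels`.
#' @export
analyze_tem_strip <- function(tess, panel_width_um = 60, overlap_frac = 0.10,
                              resolution = 2) {
  stopifnot(inherits(tess, "cell_tessellation"))
  L <- attr(tess, "strip_length_um")
  strip <- strip_as_panel(tess)
  complete <- vapply(tess, is_complete_cell, logical(1), panel = strip)
  cells <- data.frame(
    cell_id = vapply(tess, `[[`, numeric(1), "cell_id"),
    region = partition_regions(
      vapply(tess, function(cl) cl$centroid[1L], numeric(1)), c(0, L)),
    cell_area_um2 = vapply(tess, function(cl)
      polygon_area(cl$cell, check = FALSE), numeric(1)),
    nucleus_area_um2 = vapply(tess, function(cl)
      polygon_area(cl$nucleus, check = FALSE), numeric(1)),
    complete = complete)
  panels <- render_tem_panels(tess, panel_width_um, overlap_frac, resolution,
                              render = FALSE)
  sel <- select_density_panels(panels)
  inner_density <- intercellular_space_density(sel$center,
                                               resolution = resolution)
  outer_density <- mean(vapply(sel$outer, intercellular_space_density,
                               numeric(1), resolution = resolution))
  list(cells = cells, inner_density = inner_density,
       outer_density = outer_density, panels = panels,
       selected = sel)
}

#' Grouped morphometry summary
#'
#' Pools complete cells over the strips of each age group and reports,
#' per age x region, the mean and sample SD (ddof 1) of cell and nucleus
#' areas with the pooled N, and per age x region the mean and SD of the
#' per-spheroid space densities (inner = center panel, outer = mean of
#' the two outer panels).
#'
#' @param strips Named list: one element per age group (e.g. `day5`,
#'   `day20`), each a list of [analyze_tem_strip()] results.
#' @return Object of class `morphometry_summary`: list with data frames
#'   `areas` (`age`, `region`, `cell_mean`, `cell_sd`, `cell_n`,
#'   `nucleus_mean`, `nucleus_sd`) and `density` (`age`, `region`,
#'   `mean`, `sd`, `n`). Groups with fewer than 2 observations report
#'   `NA` SDs.
#' @export
summarize_groups <- function(strips) {
  area_rows <- list(); dens_rows <- list()
  for (age in names(strips)) {
    cells <- do.call(rbind, lapply(strips[[age]], `[[`, "cells"))
    cells <- cells[cells$complete, , drop = FALSE]
    for (rg in c("inner", "outer")) {
      sub <- cells[cells$region == rg, , drop = FALSE]
      area_rows[[paste(age, rg)]] <- data.frame(
        age = age, region = rg,
        cell_mean = mean(sub$cell_area_um2),
        cell_sd = if (nrow(sub) >= 2L) stats::sd(sub$cell_area_um2) else NA_real_,
        cell_n = nrow(sub),
        nucleus_mean = mean(sub$nucleus_area_um2),
        nucleus_sd = if (nrow(sub) >= 2L) stats::sd(sub$nucleus_area_um2) else NA_real_)
      dv <- vapply(strips[[age]], `[[`, numeric(1),
                   if (rg == "inner") "inner_density" else "outer_density")
      dens_rows[[paste(age, rg)]] <- data.frame(
        age = age, region = rg, mean = mean(dv),
        sd = if (length(dv) >= 2L) stats::sd(dv) else NA_real_,
        n = length(dv))
    }
  }
  structure(list(areas = do.call(rbind, area_rows),
                 density = do.call(rbind, dens_rows)),
            class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat("Cell and nucleus areas (complete cells, pooled):\n")
  a <- x$areas
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-6s %-6s cell %5.0f+/-%3.0f um^2 (N = %d)  nucleus %4.0f+/-%3.0f um^2\n",
                a$age[i], a$region[i], a$cell_mean[i], a$cell_sd[i],
                a$cell_n[i], a$nucleus_mean[i], a$nucleus_sd[i]))
  cat("Intercellular space density (%):\n")
  d <- x$density
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-6s %-6s %5.1f+/-%4.1f (n = %d spheroids)\n",
                d$age[i], d$region[i], d$mean[i], d$sd[i], d$n[i]))
  invisible(x)
}
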