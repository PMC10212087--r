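# Synthetic TEM strips: a seeded centroidal power-diagram tessellation of
# polygonal cells with nuclei, shrunk to leave calibrated intercellular
# gaps (uniform seams or bead-shaped interstitial spots), matching the
# per-region area statistics and space densities of the measured strips.

#' Region preset for the synthetic TEM generator
#'
#' @param region `"inner"` or `"outer"`.
#' @param cell_area_mean,cell_area_sd Cell cross-section area law (um^2).
#' @param nucleus_area_mean,nucleus_area_sd Nucleus area law (um^2).
#' @param target_space_density Fraction of region area left uncovered
#'   (in `[0, 1)`).
#' @param gap_style `"uniform"` (constant-width seams) or `"beaded"`
#'   (sinusoidally modulated seams forming bead-shaped interstitial
#'   spots).
#' @return Object of class `tem_region_preset`.
#' @export
tem_region_preset <- function(region, cell_area_mean, cell_area_sd,
                              nucleus_area_mean, nucleus_area_sd,
                              target_space_density,
                              gap_style = c("beaded", "uniform")) {
  gap_style <- match.arg(gap_style)
  assert_number(cell_area_mean, "cell_area_mean", positive = TRUE)
  assert_number(cell_area_sd, "cell_area_sd", positive = TRUE)
  assert_number(nucleus_area_mean, "nucleus_area_mean", positive = TRUE)
  assert_number(nucleus_area_sd, "nucleus_area_sd", positive = TRUE)
  assert_number(target_space_density, "target_space_density", nonneg = TRUE)
  abort_if(target_space_density >= 1,
           "'target_space_density' must be < 1 (a density of 1 is infeasible)")
  abort_if(nucleus_area_mean >= cell_area_mean,
           "mean nucleus area must be below mean cell area")
  structure(list(region = region, cell_area_mean = cell_area_mean,
                 cell_area_sd = cell_area_sd,
                 nucleus_area_mean = nucleus_area_mean,
                 nucleus_area_sd = nucleus_area_sd,
                 target_space_density = target_space_density,
                 gap_style = gap_style),
            class = "tem_region_preset")
}

#' TEM generator presets for the two culture ages
#'
#' Region presets carrying the measured per-region statistics: day-5
#' strips have uniform bead-lined gaps throughout, day-20 strips pack
#' larger cells with near-zero uniform gaps in the inner half and beaded
#' gaps outside.
#'
#' @param preset `"day5"` or `"day20"`.
#' @return List with elements `inner` and `outer`
#'   ([tem_region_preset()]s) plus `strip_length_um` (the group mean
#'   spheroid diameter) and `strip_height_um`.
#' @export
tem_preset <- function(preset = c("day5", "day20")) {
  preset <- match.arg(preset)
  if (preset == "day5") {
    list(inner = tem_region_preset("inner", 123, 53, 43, 19, 0.125, "beaded"),
         outer = tem_region_preset("outer", 126, 50, 41, 18, 0.140, "beaded"),
         strip_length_um = 421, strip_height_um = 80)
  } else {
    list(inner = tem_region_preset("inner", 224, 106, 71, 43, 0.024, "uniform"),
         outer = tem_region_preset("outer", 164, 86, 46, 28, 0.105, "beaded"),
         strip_length_um = 457, strip_height_um = 80)
  }
}

lognormal_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Power (Laguerre) diagram of weighted seeds clipped to a rectangle.
# Cell i = {x : |x - p_i|^2 - w_i <= |x - p_j|^2 - w_j for all j}.
# Neighbours are pruned by the exact distance of each radical axis from
# the seed versus the current cell's circumradius.
power_diagram <- function(seeds, weights, x0, x1, y0, y1) {
  n <- nrow(seeds)
  rect <- cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  dx <- outer(seeds[, 1L], seeds[, 1L], "-")
  dy <- outer(seeds[, 2L], seeds[, 2L], "-")
  dmat <- sqrt(dx^2 + dy^2)
  lapply(seq_len(n), function(i) {
    poly <- rect
    ord <- order(dmat[i, ])
    ord <- ord[ord != i]
    wmax <- max(abs(weights - weights[i]))
    rmax <- max(sqrt((poly[, 1L] - seeds[i, 1L])^2 +
                     (poly[, 2L] - seeds[i, 2L])^2))
    for (j in ord) {
      dij <- dmat[i, j]
      if (dij < 1e-9) next
      if (dij / 2 - wmax / (2 * dij) > rmax) break  # no further seed can cut
      hij <- dij / 2 + (weights[i] - weights[j]) / (2 * dij)
      if (hij >= rmax) next
      a <- 2 * (seeds[j, 1L] - seeds[i, 1L])
      b <- 2 * (seeds[j, 2L] - seeds[i, 2L])
      cc <- sum(seeds[j, ]^2) - sum(seeds[i, ]^2) + weights[i] - weights[j]
      poly <- clip_halfplane(poly, a, b, cc)
      if (nrow(poly) < 3L) return(poly[0L, , drop = FALSE])
      rmax <- max(sqrt((poly[, 1L] - seeds[i, 1L])^2 +
                       (poly[, 2L] - seeds[i, 2L])^2))
    }
    poly
  })
}

# Dart-throwing seed placement inside [xa,xb] x [0,H]. Each seed carries
# an equivalent radius from its target cell area; candidates too close to
# an already-placed seed (relative to the two radii) are mostly rejected,
# so large target cells get the room the weight fitting needs.
throw_seeds <- function(radii, xa, xb, H) {
  n <- length(radii)
  pts <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand <- c(stats::runif(1, xa, xb), stats::runif(1, 0, H))
    i <- placed + 1L
    ok <- TRUE
    if (placed > 0L) {
      d2 <- (pts[seq_len(placed), 1L] - cand[1L])^2 +
            (pts[seq_len(placed), 2L] - cand[2L])^2
      ok <- all(d2 > (0.7 * (radii[seq_len(placed)] + radii[i]))^2)
    }
    tries <- tries + 1L
    if (!ok && tries %% 200L != 0L) next  # occasional acceptance avoids deadlock
    placed <- i
    pts[placed, ] <- cand
    tries <- 0L
  }
  pts
}

#' Sample a ground-truthed cell tessellation of a TEM strip
#'
#' Builds a seeded centroidal power-diagram packing of the strip: target
#' cell areas are drawn from a lognormal matched by moments to each
#' region's mean/SD, seeds are relaxed toward centroids, and diagram
#' weights are iterated so realised areas approach their targets. Each
#' cell is then shrunk inward (constant-width or bead-modulated seams,
#' per the region's `gap_style`), with the shrink depth calibrated by
#' bisection so the uncovered fraction of each region equals its
#' `target_space_density`. Nuclei are scaled-down copies of their cell,
#' matched to the region's nucleus area law.
#'
#' @param strip_length_um Strip length along the primary axis (um).
#' @param strip_height_um Strip height (um).
#' @param presets List with `inner` and `outer` [tem_region_preset()]s.
#' @param seed Integer seed; identical seeds give identical polygon sets.
#' @return Object of class `cell_tessellation`: list of cells (each with
#'   `cell_id`, `cell` and `nucleus` polygons in strip coordinates,
#'   `region`, `centroid`), with strip metadata and the calibrated shrink
#'   depths as attributes.
#' @export
sample_cell_tessellation <- function(strip_length_um, strip_height_um,
                                     presets, seed = 1L) {
  assert_number(strip_length_um, "strip_length_um", positive = TRUE)
  assert_number(strip_height_um, "strip_height_um", positive = TRUE)
  abort_if(is.null(presets$inner) || is.null(presets$outer),
           "'presets' must carry 'inner' and 'outer' region presets")
  L <- strip_length_um; H <- strip_height_um
  inner_iv <- c(0.25 * L, 0.75 * L)
  with_seed(seed, {
    # --- target areas and seed points, per region -----------------------
    plan <- list()
    for (rg in c("inner", "outer")) {
      pr <- presets[[rg]]
      rho <- pr$target_space_density
      area_rg <- if (rg == "inner") 0.5 * L * H else 0.5 * L * H
      n <- max(3L, round(area_rg * (1 - rho) / pr$cell_area_mean))
      lp <- lognormal_params(pr$cell_area_mean, pr$cell_area_sd)
      a_cell <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
      ln <- lognormal_params(pr$nucleus_area_mean, pr$nucleus_area_sd)
      a_nuc <- stats::rlnorm(n, ln$meanlog, ln$sdlog)
      a_pre <- a_cell / (1 - rho)              # pre-shrink tiling targets
      a_pre <- a_pre * area_rg / sum(a_pre)    # tile the region exactly
      a_pre <- sort(a_pre, decreasing = TRUE)  # place big cells first
      radii <- sqrt(a_pre / pi)
      if (rg == "inner") {
        pts <- throw_seeds(radii, inner_iv[1], inner_iv[2], H)
      } else {
        nl <- round(n / 2)
        pts <- rbind(throw_seeds(radii[seq_len(nl)], 0, inner_iv[1], H),
                     throw_seeds(radii[(nl + 1L):n], inner_iv[2], L, H))
      }
      plan[[rg]] <- list(preset = pr, n = n, targets = a_pre,
                         nuc_targets = a_nuc, seeds = pts,
                         phase = stats::runif(n, 0, 2 * pi))
    }
    seeds <- rbind(plan$inner$seeds, plan$outer$seeds)
    targets <- c(plan$inner$targets, plan$outer$targets)
    region <- c(rep("inner", plan$inner$n), rep("outer", plan$outer$n))
    phases <- c(plan$inner$phase, plan$outer$phase)
    nuc_targets <- c(plan$inner$nuc_targets, plan$outer$nuc_targets)
    n <- nrow(seeds)
    # classic Laguerre initialisation: weight = equivalent radius squared
    w <- targets / pi - mean(targets / pi)

    # --- weight fitting with interleaved centroidal relaxation ----------
    # Targets are iid draws, hence exchangeable within a region: matching
    # them to cells by rank of realised area removes the geometric
    # frustration of a random assignment without changing the area law.
    for (it in 1:50) {
      polys <- power_diagram(seeds, w, 0, L, 0, H)
      areas <- vapply(polys, function(p)
        if (nrow(p) >= 3L) abs(shoelace_signed(p)) else 0, numeric(1))
      if (it %% 5L == 0L) for (rg in c("inner", "outer")) {
        idx <- which(region == rg)
        targets[idx[order(areas[idx])]] <- sort(targets[idx])
      }
      w <- w + 0.3 * (targets - areas)
      w <- w - mean(w)  # only weight differences matter
      if (it %in% c(5L, 15L, 25L))
        for (i in seq_len(n))
          if (nrow(polys[[i]]) >= 3L) seeds[i, ] <- polygon_centroid(polys[[i]])
    }
    polys <- power_diagram(seeds, w, 0, L, 0, H)
    keep <- vapply(polys, nrow, integer(1)) >= 3L
    polys <- polys[keep]; region <- region[keep]; phases <- phases[keep]
    nuc_targets <- nuc_targets[keep]
    n <- length(polys)

    # --- per-cell shrink machinery --------------------------------------
    cells_proto <- lapply(seq_len(n), function(i) {
      poly <- ensure_ccw(polys[[i]])
      ctr <- polygon_centroid(poly)
      area0 <- abs(shoelace_signed(poly))
      style <- presets[[region[i]]]$gap_style
      proto <- list(poly = poly, centroid = ctr, area0 = area0,
                    style = style, tmax = 0.35 * sqrt(area0 / pi))
      if (style == "beaded") {
        dense <- densify_polygon(poly, 1.0)
        m <- nrow(dense)
        prv <- dense[c(m, 1:(m - 1L)), , drop = FALSE]
        nxtv <- dense[c(2:m, 1L), , drop = FALSE]
        tang <- nxtv - prv
        tl <- sqrt(rowSums(tang^2)); tl[tl < 1e-12] <- 1
        # interior lies left of CCW travel: inward normal = (-ty, tx)
        normal <- cbind(-tang[, 2L], tang[, 1L]) / tl
        seg <- sqrt(rowSums((dense - prv)^2))
        u <- cumsum(seg) - seg[1L]
        proto$dense <- dense
        proto$normal <- normal
        # bead modulation: ~4 um wavelength, integer cycles per perimeter
        per <- sum(sqrt(rowSums((nxtv - dense)^2)))
        kcyc <- max(3, round(per / 4))
        proto$mod <- 1 + 0.8 * sin(2 * pi * kcyc * u / per + phases[i])
      }
      proto
    })
    shrink_cell <- function(proto, t) {
      t <- min(t, proto$tmax)
      if (t <= 0) return(proto$poly)
      if (proto$style == "uniform") {
        erode_convex(proto$poly, t)
      } else {
        proto$dense - proto$normal * 0 + proto$normal * (t * proto$mod)
      }
    }

    # --- calibrate shrink depth per region by bisection -----------------
    region_rects <- list(
      inner = list(cbind(inner_iv[1], inner_iv[2])),
      outer = list(cbind(0, inner_iv[1]), cbind(inner_iv[2], L)))
    region_area <- 0.5 * L * H
    uncovered <- function(rg, t_rg, t_other) {
      tt <- ifelse(region == rg, t_rg, t_other)
      cov <- 0
      for (i in seq_len(n)) {
        p <- shrink_cell(cells_proto[[i]], tt[i])
        if (nrow(p) < 3L) next
        for (rc in region_rects[[rg]]) {
          q <- clip_rect(p, rc[1L], rc[2L], 0, H)
          if (nrow(q) >= 3L) cov <- cov + abs(shoelace_signed(q))
        }
      }
      1 - cov / region_area
    }
    calibrate <- function(rg, t_other) {
      rho <- presets[[rg]]$target_space_density
      lo <- 0; hi <- 3
      for (it in 1:28) {
        mid <- (lo + hi) / 2
        if (uncovered(rg, mid, t_other) < rho) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    t_inner <- calibrate("inner", 0)
    t_outer <- calibrate("outer", t_inner)
    t_inner <- calibrate("inner", t_outer)  # one refinement pass
    t_by_region <- c(inner = t_inner, outer = t_outer)

    # --- final cells + nuclei -------------------------------------------
    shrunk <- lapply(seq_len(n), function(i)
      shrink_cell(cells_proto[[i]], t_by_region[[region[i]]]))
    areas <- vapply(shrunk, function(p)
      if (nrow(p) >= 3L) abs(shoelace_signed(p)) else 0, numeric(1))
    # rank-match nucleus targets to realised cell sizes within each
    # region: larger cells carry larger nuclei, which keeps the marginal
    # nucleus area law intact while making the containment clamp rare
    nuc_area <- numeric(n)
    for (rg in c("inner", "outer")) {
      idx <- which(region == rg & areas > 0)
      tgt <- sort(nuc_targets[which(region == rg)])[seq_along(idx)]
      nuc_area[idx[order(areas[idx])]] <- tgt
    }
    cells <- lapply(seq_len(n), function(i) {
      poly <- shrunk[[i]]
      if (nrow(poly) < 3L) return(NULL)
      a <- areas[i]
      ctr <- polygon_centroid(poly)
      s <- sqrt(min(nuc_area[i], 0.8 * a) / a)
      s <- max(s, 0.15)
      list(cell_id = i, cell = poly,
           nucleus = polygon_scale(poly, ctr, s),
           region = region[i], centroid = ctr)
    })
    cells <- Filter(Negate(is.null), cells)
    structure(cells, class = "cell_tessellation",
              strip_length_um = L, strip_height_um = H,
              shrink_um = t_by_region, seed = seed,
              presets = presets)
  })
}

#' @export
print.cell_tessellation <- function(x, ...) {
  cat(sprintf("cell_tessellation: %d cells on a %.0f x %.0f um strip (seed %d)\n",
              length(x), attr(x, "strip_length_um"),
              attr(x, "strip_height_um"), attr(x, "seed")))
  invisible(x)
}

#' Split a tessellated strip into overlapping TEM panels
#'
#' Consecutive panels of `panel_width_um` overlap by `overlap_frac` of
#' their width; the first and last panels contain the spheroid edge
#' (the strip ends) and are flagged. Each panel carries the cell and
#' nucleus polygons clipped to its interval, a `clipped` flag marking
#' cells cut by the panel bounds, and a grayscale raster (light gaps,
#' darker cell interiors, darkest nuclei).
#'
#' @param tess A [sample_cell_tessellation()].
#' @param panel_width_um Panel width (um), at most the strip length.
#' @param overlap_frac Overlap between consecutive panels as a fraction
#'   of the panel width (default 0.10).
#' @param resolution Raster resolution (px/um, default 2).
#' @param render If `FALSE`, skip rasters (geometry only).
#' @return List of `tem_panel` objects: `panel_id`, `x_start_um`,
#'   `x_end_um`, `contains_spheroid_edge`, `cells` (clipped polygons with
#'   flags), `raster`.
#' @export
render_tem_panels <- function(tess, panel_width_um = 60, overlap_frac = 0.10,
                              resolution = 2, render = TRUE) {
  stopifnot(inherits(tess, "cell_tessellation"))
  L <- attr(tess, "strip_length_um"); H <- attr(tess, "strip_height_um")
  abort_if(panel_width_um > L, "'panel_width_um' must not exceed the strip length")
  if (resolution < 2)
    log_msg("synth-tem", sprintf(
      "resolution %.2g px/um may not resolve the narrowest gaps", resolution),
      level = "warn")
  stride <- panel_width_um * (1 - overlap_frac)
  starts <- seq(0, L - panel_width_um, by = stride)
  if (max(starts) < L - panel_width_um - 1e-9)
    starts <- c(starts, L - panel_width_um)
  lapply(seq_along(starts), function(k) {
    x0 <- starts[k]; x1 <- starts[k] + panel_width_um
    cells <- lapply(tess, function(cl) {
      cp <- clip_rect(cl$cell, x0, x1, 0, H)
      if (nrow(cp) < 3L) return(NULL)
      np <- clip_rect(cl$nucleus, x0, x1, 0, H)
      clipped <- min(cl$cell[, 1L]) <= x0 + 1e-9 ||
                 max(cl$cell[, 1L]) >= x1 - 1e-9
      list(cell_id = cl$cell_id, cell = cp,
           nucleus = if (nrow(np) >= 3L) np else NULL,
           full_cell = cl$cell, full_nucleus = cl$nucleus,
           region = cl$region, centroid = cl$centroid, clipped = clipped)
    })
    cells <- Filter(Negate(is.null), cells)
    raster <- NULL
    if (render) {
      nx <- round(panel_width_um * resolution)
      ny <- round(H * resolution)
      cmask <- fill_polygons_mask(lapply(cells, `[[`, "cell"),
                                  x0, 0, nx, ny, resolution)
      nmask <- fill_polygons_mask(Filter(Negate(is.null),
                                         lapply(cells, `[[`, "nucleus")),
                                  x0, 0, nx, ny, resolution)
      raster <- matrix(0.88, ny, nx)
      raster[cmask] <- 0.55
      raster[nmask] <- 0.25
    }
    structure(list(panel_id = k, x_start_um = x0, x_end_um = x1,
                   contains_spheroid_edge = (x0 <= 1e-9 || x1 >= L - 1e-9),
                   strip_height_um = H, resolution = resolution,
                   cells = cells, raster = raster),
              class = "tem_panel")
  })
}

#' A single panel spanning the whole strip
#'
#' Convenience wrapper used to apply panel-based operations (such as the
#' complete-cell rule) to the stitched strip as one image.
#' @param tess A [sample_cell_tessellation()].
#' @return A `tem_panel` covering `[0, strip_length]`.
#' @export
strip_as_panel <- function(tess) {
  render_tem_panels(tess, panel_width_um = attr(tess, "strip_length_um"),
                    overlap_frac = 0, render = FALSE)[[1L]]
}
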