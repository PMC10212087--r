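# Shared fixtures, built in code and memoised so expensive synthetic
# runs are generated once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Full-preset pipeline configuration for one age group.
age_config <- function(age) default_config(age)

# One tracked-and-fitted synthetic compression run (memoised).
mech_run <- function(age, seed, noise_sd = 0.02) {
  memo(sprintf("mech_%s_%d_%g", age, seed, noise_sd), {
    cfg <- age_config(age)
    cfg$noise_sd <- noise_sd
    suppressWarnings(run_compression_analysis(cfg, seed))
  })
}

# Analysed full-preset TEM strips (memoised).
tem_strips <- function(age, seeds = 1:3) {
  memo(sprintf("tem_%s_%s", age, paste(seeds, collapse = "-")), {
    pr <- tem_preset(age)
    lapply(seeds, function(s) {
      tess <- sample_cell_tessellation(pr$strip_length_um,
                                       pr$strip_height_um, pr, seed = s)
      an <- analyze_tem_strip(tess)
      an$tess <- tess
      an
    })
  })
}

# A small strip preset for fast generator tests.
small_tem_preset <- function(rho_inner = 0.10, rho_outer = 0.14,
                             style = "beaded") {
  list(inner = tem_region_preset("inner", 120, 50, 42, 18, rho_inner, style),
       outer = tem_region_preset("outer", 125, 50, 42, 18, rho_outer, style))
}

small_tessellation <- function(seed = 1, rho_inner = 0.10, rho_outer = 0.14,
                               style = "beaded") {
  sample_cell_tessellation(160, 60, small_tem_preset(rho_inner, rho_outer,
                                                     style), seed = seed)
}

# Exact polygon-based uncovered fraction of a region of a tessellation.
region_uncovered_exact <- function(tess, region = c("inner", "outer")) {
  region <- match.arg(region)
  L <- attr(tess, "strip_length_um"); H <- attr(tess, "strip_height_um")
  rects <- if (region == "inner") list(c(0.25 * L, 0.75 * L))
           else list(c(0, 0.25 * L), c(0.75 * L, L))
  cov <- 0
  for (cl in tess) for (rc in rects) {
    q <- spheromech:::clip_rect(cl$cell, rc[1], rc[2], 0, H)
    if (nrow(q) >= 3) cov <- cov + polygon_area(q, check = FALSE)
  }
  1 - cov / (0.5 * L * H)
}

# Random convex polygon: convex hull of points scattered in a disc.
random_convex_polygon <- function(n = 12, r = 10, cx = 0, cy = 0) {
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- r * sqrt(stats::runif(n, 0.2, 1))
  x <- cx + rad * cos(ang); y <- cy + rad * sin(ang)
  h <- grDevices::chull(x, y)
  cbind(x[h], y[h])
}

# Ground-truth tip positions of a simulated run as a data frame.
truth_positions <- function(sim, which = c("reference", "loaded")) {
  which <- match.arg(which)
  key <- paste0(which, "_positions_px")
  do.call(rbind, lapply(seq_along(sim$truth[[key]]), function(i) {
    p <- sim$truth[[key]][[i]]
    data.frame(step = i - 1L, tip = c("upper", "lower"),
               x = p[, 1], y = p[, 2])
  }))
}

rms_tracking_error <- function(traj, truth) {
  m <- merge(as.data.frame(traj), truth, by = c("step", "tip"))
  sqrt(mean((m$x_px - m$x)^2 + (m$y_px - m$y)^2))
}
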