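# End-to-end orchestration: single-run compression analysis, the two
# pipeline arms, and the deterministic run-all entry point with an
# artifact manifest.

#' Analyse one synthetic compression run end to end
#'
#' Simulates a reference + loaded pair, tracks both runs, converts the
#' tracked positions into deflections, forces and a compression series,
#' and fits the Young's modulus. Tracking is initialised from the
#' commanded step-0 geometry (known without ground truth).
#'
#' @param cfg A `pipeline_config` (see [default_config()]); the spheroid
#'   is taken from `cfg$diameter_um` / `cfg$youngs_modulus_pa`.
#' @param seed Integer seed for the synthetic run.
#' @return List with `estimate` ([fit_modulus()] result), `curve`,
#'   `deflections`, `trajectories` (loaded + reference), and `sim`.
#' @export
run_compression_analysis <- function(cfg, seed) {
  profile <- build_actuation_profile(cfg$volts_per_step, cfg$max_volts,
                                     cfg$gain_um_per_v)
  cant <- cantilever_spec(spring_constant = cfg$spring_constant)
  sph <- spheroid_spec(cfg$diameter_um, cfg$youngs_modulus_pa,
                       cfg$poisson_ratio)
  spec <- compression_image_spec(cfg, sph)
  sim <- simulate_compression_experiment(
    profile, cant, sph, spec = spec, noise_sd = cfg$noise_sd, seed = seed,
    initial_gap_um = cfg$initial_gap_um)
  init <- initial_tip_positions(cfg, sph, spec)
  ref <- track_tips(sim$reference, sim$template, init,
                    search_radius = cfg$search_radius,
                    score_floor = cfg$score_floor, run = "reference")
  lod <- track_tips(sim$loaded, sim$template, init,
                    search_radius = cfg$search_radius,
                    score_floor = cfg$score_floor, run = "loaded")
  defl <- compute_deflections(lod, ref, cfg$pixel_pitch_um)
  force <- force_from_deflection(defl, cfg$spring_constant)
  comp <- compression_series(defl$separation_um, sph$diameter_um)
  curve <- force_displacement_curve(comp$delta_um, force,
                                    sph$diameter_um / 2, cfg$poisson_ratio,
                                    comp$contact_step)
  list(estimate = fit_modulus(curve), curve = curve, deflections = defl,
       trajectories = list(reference = ref, loaded = lod), sim = sim)
}

# Frame geometry sized to hold both tips over the whole actuation range.
compression_image_spec <- function(cfg, sph) {
  s0 <- sph$diameter_um + cfg$initial_gap_um
  half_px <- ceiling(s0 / 2 / cfg$pixel_pitch_um)
  image_spec(width_px = 80L,
             height_px = 2L * (half_px + 20L),
             pixel_pitch_um = cfg$pixel_pitch_um)
}

initial_tip_positions <- function(cfg, sph, spec) {
  s0 <- sph$diameter_um + cfg$initial_gap_um
  cx <- (spec$width_px + 1) / 2
  cy <- (spec$height_px + 1) / 2
  h <- s0 / 2 / spec$pixel_pitch_um
  rbind(upper = c(cx, cy - h), lower = c(cx, cy + h))
}

#' Run the mechanics arm for one age group
#'
#' @param cfg A `pipeline_config`.
#' @param seeds Integer seeds, one synthetic run each.
#' @return List with `estimates` data frame (`run`, `seed`, `E_pa`,
#'   `residual_n`, `n_points`) and the per-run results.
#' @export
run_mechanics_arm <- function(cfg, seeds) {
  runs <- lapply(seq_along(seeds), function(i)
    run_compression_analysis(cfg, seeds[i]))
  est <- do.call(rbind, lapply(seq_along(runs), function(i)
    data.frame(run = i, seed = seeds[i],
               E_pa = runs[[i]]$estimate$youngs_modulus_pa,
               residual_n = runs[[i]]$estimate$residual_n,
               n_points = runs[[i]]$estimate$n_points)))
  list(estimates = est, runs = runs)
}

#' Run the TEM morphometry arm for one age group
#'
#' @param cfg A `pipeline_config` (TEM preset follows `cfg$preset`).
#' @param seeds Integer seeds, one strip each.
#' @return List with per-strip [analyze_tem_strip()] results and the
#'   tessellations.
#' @export
run_tem_arm <- function(cfg, seeds) {
  pr <- tem_preset(if (cfg$preset == "day20") "day20" else "day5")
  strips <- lapply(seeds, function(s) {
    tess <- sample_cell_tessellation(cfg$strip_length_um,
                                     cfg$strip_height_um, pr, seed = s)
    an <- analyze_tem_strip(tess, cfg$panel_width_um, cfg$overlap_frac,
                            cfg$resolution)
    an$tess <- tess
    an
  })
  strips
}

#' Run the complete pipeline on synthetic data
#'
#' Executes both arms for both age groups (day-5 and day-20 presets),
#' assembles the report, writes every artifact under `out_dir`, and
#' writes a manifest listing each output file with its MD5 content hash.
#' All randomness derives from `seed`; repeated invocations with the
#' same seed produce identical manifests.
#'
#' @param config A `pipeline_config` (instrument and sampling settings;
#'   spheroid and TEM statistics follow the age presets).
#' @param seed Master integer seed.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `manifest` (data frame `file`, `md5`),
#'   `report`, `summary`, `moduli` and `out_dir`.
#' @export
run_all <- function(config = default_config(), seed = 1L, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ages <- c("day5", "day20")
  offsets <- c(day5 = 0L, day20 = 500L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  write_config(config, file.path(out_dir, "config.yaml"))
  moduli_rows <- list(); curve_rows <- list(); traj_rows <- list()
  strips_by_age <- list(); cell_rows <- list(); dens_rows <- list()
  moduli <- list()

  for (age in ages) {
    cfg <- config
    cfg$preset <- age
    sph <- spheroid_preset(age)
    cfg$diameter_um <- sph$diameter_um
    cfg$youngs_modulus_pa <- sph$youngs_modulus_pa
    tp <- tem_preset(age)
    cfg$strip_length_um <- tp$strip_length_um

    mech_seeds <- seed * 1000L + offsets[[age]] + seq_len(config$n_runs)
    arm <- stage(paste0("mechanics/", age), run_mechanics_arm(cfg, mech_seeds))
    moduli_rows[[age]] <- cbind(age = age, arm$estimates)
    moduli[[age]] <- list(mean_pa = mean(arm$estimates$E_pa),
                          sd_pa = stats::sd(arm$estimates$E_pa),
                          n = nrow(arm$estimates))
    for (i in seq_along(arm$runs)) {
      r <- arm$runs[[i]]
      curve_rows[[paste(age, i)]] <- data.frame(
        age = age, run = i, step = seq_along(r$curve$delta_um) - 1L,
        delta_um = r$curve$delta_um, force_nN = r$curve$force_n * 1e9)
      for (rt in c("reference", "loaded"))
        traj_rows[[paste(age, i, rt)]] <- cbind(
          age = age, run = i, run_type = rt,
          as.data.frame(r$trajectories[[rt]]))
      if (isTRUE(config$write_images)) {
        base <- file.path(out_dir, "images", sprintf("%s_run%02d", age, i))
        write_image_sequence(r$sim$reference, file.path(base, "reference"))
        write_image_sequence(r$sim$loaded, file.path(base, "loaded"))
      }
    }

    tem_seeds <- seed * 1000L + offsets[[age]] + 100L + seq_len(config$n_strips)
    strips <- stage(paste0("tem/", age), run_tem_arm(cfg, tem_seeds))
    strips_by_age[[age]] <- strips
    for (s in seq_along(strips)) {
      cell_rows[[paste(age, s)]] <- cbind(age = age, strip = s,
                                          strips[[s]]$cells)
      dens_rows[[paste(age, s)]] <- data.frame(
        age = age, strip = s,
        inner_density = strips[[s]]$inner_density,
        outer_density = strips[[s]]$outer_density)
      if (isTRUE(config$write_images))
        write_polygons_geojson(
          strips[[s]]$tess,
          file.path(out_dir, sprintf("tem_polygons_%s_%02d.geojson", age, s)))
    }
  }

  summary <- stage("summarize", summarize_groups(strips_by_age))
  comparisons <- stage("compare", {
    out <- list()
    cells <- do.call(rbind, cell_rows)
    for (age in ages) {
      cc <- cells[cells$age == age & cells$complete, ]
      for (kind in c("cell", "nucleus")) {
        col <- paste0(kind, "_area_um2")
        out[[paste0(age, "_", kind)]] <- welch_t_test(
          cc[cc$region == "inner", col], cc[cc$region == "outer", col],
          labels = paste(age, c("inner", "outer")))
      }
      dd <- do.call(rbind, dens_rows)
      dd <- dd[dd$age == age, ]
      if (nrow(dd) >= 2L)
        out[[paste0(age, "_density")]] <- welch_t_test(
          dd$inner_density, dd$outer_density,
          labels = paste(age, c("inner", "outer")))
    }
    if (moduli$day20$n >= 2L && moduli$day5$n >= 2L)
      out[["stiffness"]] <- welch_from_summary(
        moduli$day20$mean_pa, moduli$day20$sd_pa, moduli$day20$n,
        moduli$day5$mean_pa, moduli$day5$sd_pa, moduli$day5$n,
        labels = c("day20", "day5"))
    out
  })
  report <- stage("report",
                  build_report(summary, comparisons, moduli,
                               strict = isTRUE(config$strict)))

  wcsv <- function(x, name) {
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(do.call(rbind, moduli_rows), "moduli.csv")
  wcsv(do.call(rbind, curve_rows), "curves.csv")
  wcsv(do.call(rbind, traj_rows), "trajectories.csv")
  wcsv(do.call(rbind, cell_rows), "morphometry_cells.csv")
  wcsv(do.call(rbind, dens_rows), "densities.csv")
  write_report_csv(report, file.path(out_dir, "report.csv"))
  write_report_md(report, file.path(out_dir, "report.md"))
  jsonlite::write_json(
    lapply(comparisons, function(cmp)
      list(labels = cmp$labels, t = cmp$t, df = cmp$df, p = cmp$p,
           mark = cmp$mark)),
    file.path(out_dir, "comparisons.json"), auto_unbox = TRUE, digits = NA)

  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE), "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("run-all", sprintf("wrote %d artifacts to %s", nrow(manifest),
                             out_dir))
  invisible(list(manifest = manifest, report = report, summary = summary,
                 moduli = moduli, out_dir = out_dir))
}
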