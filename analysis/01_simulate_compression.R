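#!/usr/bin/env Rscript
# Step 1: generate one synthetic microtweezer compression experiment per
# age preset and record the ground truth the later steps will try to
# recover. Writes results/ground_truth_curves.csv and a few example
# frames under results/frames/.

suppressPackageStartupMessages(library(spheromech))
dir.create("results/frames", recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (age in c("day5", "day20")) {
  cfg <- default_config(age)
  profile <- build_actuation_profile(cfg$volts_per_step, cfg$max_volts,
                                     cfg$gain_um_per_v)
  sim <- simulate_compression_experiment(
    profile, cantilever_spec(spring_constant = cfg$spring_constant),
    spheroid_preset(age), spec = spheromech:::compression_image_spec(
      cfg, spheroid_preset(age)),
    noise_sd = cfg$noise_sd, seed = 1L, initial_gap_um = cfg$initial_gap_um)
  tr <- sim$truth
  rows[[age]] <- data.frame(
    age = age, step = tr$step,
    commanded_separation_um = tr$commanded_separation_um,
    deflection_um = tr$deflection_um,
    compression_um = tr$compression_um,
    force_nN = tr$force_n * 1e9)
  write_image_sequence(sim$loaded[1:4],
                       file.path("results/frames", age), prefix = "loaded")
  first_contact <- which(tr$compression_um > 0)[1] - 1L
  cat(sprintf(
    "%s: %d steps; contact at step %d; final compression %.0f um (%.0f%% of diameter); peak force %.2f uN\n",
    age, profile$n_steps, first_contact, max(tr$compression_um),
    100 * max(tr$compression_um) / spheroid_preset(age)$diameter_um,
    max(tr$force_n) * 1e6))
}
truth <- do.call(rbind, rows)
write.csv(truth, "results/ground_truth_curves.csv", row.names = FALSE)
cat(sprintf("day-20/day-5 peak-force ratio in the generated truth: %.2f\n",
            max(rows$day20$force_nN) / max(rows$day5$force_nN)))
cat("wrote results/ground_truth_curves.csv\n")
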