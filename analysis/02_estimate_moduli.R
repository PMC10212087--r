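#!/usr/bin/env Rscript
# Step 2: run the full stiffness pipeline (template-matching tip
# tracking against the no-spheroid reference, deflection -> force via
# the cantilever spring constant, plate-contact Hertz inversion) on six
# seeded synthetic experiments per age preset. Writes results/moduli.csv.

suppressPackageStartupMessages(library(spheromech))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (age in c("day5", "day20")) {
  cfg <- default_config(age)
  for (s in 1:6) {
    res <- suppressWarnings(run_compression_analysis(cfg, seed = s))
    rows[[paste(age, s)]] <- data.frame(
      age = age, seed = s,
      E_pa = res$estimate$youngs_modulus_pa,
      residual_nN = res$estimate$residual_n * 1e9,
      n_points = res$estimate$n_points)
  }
  E <- vapply(rows[paste(age, 1:6)], `[[`, numeric(1), "E_pa")
  cat(sprintf("%s: recovered E = %.0f +/- %.0f Pa over %d runs (preset %.0f Pa)\n",
              age, mean(E), sd(E), length(E),
              spheroid_preset(age)$youngs_modulus_pa))
}
moduli <- do.call(rbind, rows)
write.csv(moduli, "results/moduli.csv", row.names = FALSE)

r <- force_ratio(mean(moduli$E_pa[moduli$age == "day20"]),
                 mean(moduli$E_pa[moduli$age == "day5"]))
cat(sprintf("model force ratio (day20/day5) at equal compression: %.2f\n", r))
cat("wrote results/moduli.csv\n")
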