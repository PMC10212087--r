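#!/usr/bin/env Rscript
# Step 4: group comparisons (Welch's t) and report assembly from the
# tables written by steps 2 and 3. Writes results/report.csv,
# results/report.md and results/comparisons.json.

suppressPackageStartupMessages(library(spheromech))
for (f in c("results/moduli.csv", "results/morphometry_cells.csv",
            "results/densities.csv"))
  if (!file.exists(f))
    stop(sprintf("missing %s -- run analysis steps 2 and 3 first", f))

moduli_tab <- read.csv("results/moduli.csv")
cells <- read.csv("results/morphometry_cells.csv")
dens <- read.csv("results/densities.csv")

strips_by_age <- lapply(split(cells, cells$age), function(cc)
  lapply(split(cc, cc$strip), function(sc) {
    d <- dens[dens$age == sc$age[1] & dens$strip == sc$strip[1], ]
    list(cells = sc, inner_density = d$inner_density,
         outer_density = d$outer_density)
  }))
summary <- summarize_groups(strips_by_age)

comparisons <- list()
for (age in c("day5", "day20")) {
  cc <- cells[cells$age == age & cells$complete, ]
  for (kind in c("cell", "nucleus")) {
    col <- paste0(kind, "_area_um2")
    comparisons[[paste0(age, "_", kind)]] <- welch_t_test(
      cc[cc$region == "inner", col], cc[cc$region == "outer", col],
      labels = paste(age, c("inner", "outer")))
  }
  dd <- dens[dens$age == age, ]
  comparisons[[paste0(age, "_density")]] <- welch_t_test(
    dd$inner_density, dd$outer_density,
    labels = paste(age, c("inner", "outer")))
}
moduli <- lapply(split(moduli_tab, moduli_tab$age), function(m)
  list(mean_pa = mean(m$E_pa), sd_pa = sd(m$E_pa), n = nrow(m)))
comparisons$stiffness <- welch_from_summary(
  moduli$day20$mean_pa, moduli$day20$sd_pa, moduli$day20$n,
  moduli$day5$mean_pa, moduli$day5$sd_pa, moduli$day5$n,
  labels = c("day20", "day5"))

for (nm in names(comparisons)) { cat(nm, ": "); print(comparisons[[nm]]) }

report <- build_report(summary, comparisons, moduli)
write_report_csv(report, "results/report.csv")
write_report_md(report, "results/report.md")
jsonlite::write_json(
  lapply(comparisons, function(x)
    list(labels = x$labels, t = x$t, df = x$df, p = x$p, mark = x$mark)),
  "results/comparisons.json", auto_unbox = TRUE, digits = NA)
cat(sprintf("stiffness: day20 %.0f +/- %.0f Pa vs day5 %.0f +/- %.0f Pa (p = %.2g); force ratio %.2f\n",
            moduli$day20$mean_pa, moduli$day20$sd_pa,
            moduli$day5$mean_pa, moduli$day5$sd_pa,
            comparisons$stiffness$p, report$force_ratio))
cat("wrote results/report.{csv,md} and results/comparisons.json\n")
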