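#!/usr/bin/env Rscript
# Convert counts and split masses to fluxes, compute depth-averaged cell
# fluxes per deployment with their fold changes, and the cell POC flux
# as a percentage of bulk POC. Run after 01_simulate.R.

suppressPackageStartupMessages(library(gelflux))

for (site in c("bloom", "layer")) {
  data <- read_dataset(file.path("results/data", site))
  ft <- cell_flux_table(data$counts)
  bt <- bulk_flux_table(data$bulk_masses, data$trap_samples)
  dir <- file.path("results/fluxes", site)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(ft, file.path(dir, "cell_fluxes.csv"), row.names = FALSE)
  write.csv(bt, file.path(dir, "bulk_fluxes.csv"), row.names = FALSE)

  # depth-averaged total cell flux per deployment and fold changes
  tot <- tapply(ft$flux_cells_m2_d, ft$sample_id, sum)
  meta <- data$trap_samples
  dep_avg <- vapply(sort(unique(meta$deployment)), function(d) {
    ids <- meta$sample_id[meta$deployment == d]
    recs <- lapply(tot[ids], flux_record, sigma = 0, units = "cells_m2_d")
    depth_average_flux(recs)$value
  }, numeric(1))
  cat(sprintf("\n%s depth-averaged cell flux by deployment (1e6 cells/m2/d): %s\n",
              toupper(site), paste(round(dep_avg / 1e6, 3), collapse = ", ")))
  for (d in 2:length(dep_avg)) {
    fc <- fold_change(flux_record(dep_avg[d], 0, "cells_m2_d"),
                      flux_record(dep_avg[d - 1], 0, "cells_m2_d"))
    cat(sprintf("  deployment %d vs %d: %.1f-fold\n", d, d - 1, fc$value))
  }

  # cell POC flux as % of bulk POC per sample
  pg <- cell_carbon(sphere_volume(45))
  pct <- vapply(bt$sample_id, function(id) {
    sub <- ft[ft$sample_id == id, ]
    cellrec <- flux_record(sum(sub$flux_cells_m2_d), sqrt(sum(sub$sigma^2)),
                           "cells_m2_d", n_counted = sum(sub$n_counted))
    bulkrec <- flux_record(bt$poc_flux_mmolC_m2_d[bt$sample_id == id],
                           bt$sigma[bt$sample_id == id], "mmolC_m2_d")
    percent_of_bulk_poc(cellrec, pg, bulkrec)$value
  }, numeric(1))
  write.csv(data.frame(sample_id = bt$sample_id, cell_poc_percent = pct),
            file.path(dir, "cell_poc_percent.csv"), row.names = FALSE)
  cat(sprintf("  cell POC as %% of bulk POC: mean %.1f%% (range %.1f-%.1f%%)\n",
              mean(pct), min(pct), max(pct)))
}
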