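#!/usr/bin/env Rscript
# Covariation of flux classes: Spearman rank correlation between the
# solitary-cell POC flux and the small-detrital POC flux, and PCA
# loadings of all flux variables on the first two components.
# Run after 01_simulate.R.

suppressPackageStartupMessages(library(gelflux))

for (site in c("bloom", "layer")) {
  data <- read_dataset(file.path("results/data", site))
  ft <- cell_flux_table(data$counts)
  X <- flux_feature_table(ft, data$detrital_fluxes)

  sp <- spearman_rho(X[, "cell_poc"], X[, "small_detrital"],
                     n_perm = 9999, seed = 21)
  pca <- pca_first_two_loadings(X)

  dir <- file.path("results/covariation", site)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(variable = rownames(pca$loadings), pca$loadings,
                       check.names = FALSE),
            file.path(dir, "pca_loadings.csv"), row.names = FALSE)
  write.csv(data.frame(sample_id = rownames(pca$scores), pca$scores),
            file.path(dir, "pca_scores.csv"), row.names = FALSE)
  write.csv(data.frame(statistic = c("rho", "p_value", "n"),
                       value = c(sp$rho, sp$p_value, sp$n)),
            file.path(dir, "spearman.csv"), row.names = FALSE)

  cat(sprintf("\n%s: cell POC vs small-detrital POC Spearman rho %.2f (p %.3f, n %d)\n",
              toupper(site), sp$rho, sp$p_value, sp$n))
  cat(sprintf("  PC1/PC2 explain %.0f%% / %.0f%% of variance\n",
              100 * pca$explained_variance[1],
              100 * pca$explained_variance[2]))
  l1 <- pca$loadings[, 1]
  cat(sprintf("  PC1 loadings: %s\n",
              paste(sprintf("%s %.2f", names(l1), l1), collapse = ", ")))
}
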