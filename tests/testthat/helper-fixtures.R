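# Shared fixtures: small configurations reused across test files.

# Minimal fast scenario: one platform, few depths, few taxa.
small_config <- function(seed = 1L, ...) {
  scenario_config(
    depths_m = c(100, 200, 300, 400, 500),
    true_flux_surface = c(Thalassiosira = 2e5, Thalassionema = 1e5,
                          Fragilariopsis = 8e4),
    full_gel_taxa = character(),
    seed = seed,
    ...)
}

# Layer scenario with a dense depth grid for translation-inversion tests.
layer_config <- function(seed = 1L, speed = 6.6, n_platforms = 1L,
                         platform_cv = 0.22) {
  scenario_config(
    depths_m = seq(60, 500, by = 20),
    true_flux_surface = c(Fragilariopsis = 3e5, Thalassiosira = 1e5),
    depth_shape = "layer",
    layer_taxon = "Fragilariopsis",
    layer_center_m = 430,
    layer_width_m = 35,
    layer_speed_m_d = speed,
    platform_cv = platform_cv,
    n_platforms = n_platforms,
    full_gel_taxa = character(),
    seed = seed)
}

# Random small community matrix with positive entries.
random_community <- function(n, p, seed) {
  set.seed(seed)
  M <- matrix(stats::rgamma(n * p, shape = 2, rate = 1e-5), n, p)
  rownames(M) <- paste0("S", seq_len(n))
  colnames(M) <- paste0("taxon", seq_len(p))
  M
}
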