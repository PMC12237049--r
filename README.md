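# gelflux

Fluxes of solitary sinking phytoplankton cells from sediment-trap gel
layers.

Most sinking organic carbon reaches the deep ocean inside aggregates and
fecal pellets, but polyacrylamide gel layers placed at the bottom of
sediment-trap tubes reveal another pool: phytoplankton cells sinking as
solitary individuals. `gelflux` is for biological oceanographers working
with such gel-layer counts and companion bulk carbon collections. It
covers the full analysis chain:

* **Flux quantification.** A count of `N` cells over surveyed gel area
  `A` during collection period `T` gives the number flux `F = N/(A·T)`
  with Poisson counting uncertainty `σ = √N/(A·T)` (relative error
  `1/√N`). Bulk POC fluxes come from replicate split masses divided by
  the split fraction, duration and the combined tube area (0.0226 m²),
  with replicate spread as the uncertainty. Derived quantities — depth
  averages, fold changes, cell carbon via the spherical-biovolume
  allometry `C = a·V^b`, percent-of-bulk-POC, gel-vs-bulk solitary
  fractions — propagate both error sources in quadrature.
* **Community structure.** Bray–Curtis dissimilarity
  `Σ|x−y| / Σ(x+y)` among samples, one-way PERMANOVA by label
  permutation of the pseudo-F computed directly from the dissimilarity
  matrix, metric/nonmetric 2-D ordination, and a similarity network
  linking samples with dissimilarity strictly below 0.25, partitioned
  into connected components with mean cluster compositions.
* **Covariation.** Spearman rank correlation (permutation p-values)
  between solitary-cell POC flux and detrital particle-class POC
  fluxes, and PCA loadings of min–max-normalised flux variables.
* **Sinking speed.** The geometric minimum speed for gel capture
  (tube height / collection period), and a rigid-translation inversion:
  the loss in depth-integrated flux of one taxon between deployments,
  `ΔI`, is matched to the early profile's integral over its bottom `d`
  metres and solved for `d` by bisection; speed = `d/Δt`.
* **Synthetic data with ground truth.** `generate_scenario()` emulates
  the four input tables with Poisson counting noise, lognormal
  platform-to-platform variability (CV constrained to the observed
  0.22–0.79 range), replicate-split noise, copula-coupled detrital
  fluxes and an optional taxon layer translating at a known speed, so
  every estimator can be validated by parameter recovery.

## Worked example

```r
library(gelflux)

# 657 cells counted over a 0.0113 m^2 gel surveyed for 1.8 days
f <- number_flux(count = 657, surveyed_area_m2 = 0.0113, duration_d = 1.8)
f
#> <flux_record> 32300.9 +/- 1260.18 cells_m2_d (n counted = 657)

# three replicate splits (umol C) of an 8-way split, 1.8 d, 0.0226 m^2
bulk <- bulk_poc_flux(c(0.95, 1.00, 1.08), split_fraction = 1/8,
                      duration_d = 1.8, area_m2 = 0.0226)
bulk
#> <flux_record> 198.623 +/- 12.8957 umolC_m2_d

# carbon content of a 45-um cell and the cells' share of bulk POC
pg <- cell_carbon(sphere_volume(45))       # 1545 pg C per cell
percent_of_bulk_poc(f, pg,
                    flux_record(bulk$value / 1000, bulk$sigma / 1000,
                                "mmolC_m2_d"))
#> <flux_record> 2.09162 +/- 0.15843 percent

# a synthetic deep layer translating at 6.6 m/d, recovered from its
# noise-free profiles between deployments 2 and 3
ds <- generate_scenario(scenario_config(depth_shape = "layer",
                                        layer_speed_m_d = 6.6, seed = 7))
infer_translation_speed(truth_profile(ds, "Fragilariopsis", 2),
                        truth_profile(ds, "Fragilariopsis", 3),
                        delta_t_d = 7)
#> <sinking_speed_estimate> 6.65 m/d (depth 46.6 m over 7 d)
```

The flux record reads: 3.2 × 10⁴ cells m⁻² d⁻¹ with a 3.9% counting
error (1/√657). The percent record says solitary cells carry about 2.1%
of the bulk POC flux in this example. The recovered 6.65 m d⁻¹ differs
from the configured 6.6 m d⁻¹ only through the trapezoidal integration
of the 50 m depth grid.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full
study on two synthetic scenarios (a bloom-export site with coupled
cell/detrital fluxes, and a deep-layer site with a translating
*Fragilariopsis* population), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # generate both scenario datasets
Rscript analysis/02_fluxes.R     # cell/bulk fluxes, fold changes, % POC
Rscript analysis/03_community.R  # Bray-Curtis, PERMANOVA, MDS, network
Rscript analysis/04_covariation.R# Spearman + PCA loadings
Rscript analysis/05_sinking.R    # capture speeds + translation inversion
```

`run_pipeline()` chains the same stages programmatically and writes a
result bundle whose files carry provenance headers (package version,
config hash, seed); identical config and seed give byte-identical
output.

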