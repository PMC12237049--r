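---
title: "Quantifying solitary sinking phytoplankton cells from sediment-trap gel layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying solitary sinking phytoplankton cells from sediment-trap gel layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelflux)
```

## The measurement problem

Sediment traps intercept sinking particles over a known collection area
and period. A polyacrylamide gel layer at the base of a trap tube
captures those particles intact and spatially separated, so individual
phytoplankton cells that sank on their own — rather than embedded in
aggregates or fecal pellets — can be identified and counted under a
microscope. `gelflux` turns such counts, together with bulk carbon
masses from companion brine tubes, into number and carbon fluxes with
propagated uncertainties, and supports the downstream questions those
fluxes raise: how does community composition change over depth and time,
do cell fluxes covary with detrital particle fluxes, and how fast must
the cells have been sinking?

## Flux estimation and its uncertainty model

A count of $N$ cells over a surveyed gel area $A$ (m$^2$) during a
collection period $T$ (d) estimates the number flux

$$ F = \frac{N}{A\,T}, \qquad \sigma_F = \frac{\sqrt{N}}{A\,T}, $$

the Poisson standard deviation of the count divided by the same
normalisation. The relative uncertainty is therefore $1/\sqrt{N}$: a
few hundred counted cells give a few-percent counting error, which is
why the package reports `n_counted` on every count-derived
`flux_record`. Cells are detected at two magnification tiers — a gel
subsample at high magnification for small abundant cells, and the full
gel surface for large rare ones. Tiers keep their own surveyed areas;
when a taxon is counted at both, the tier fluxes are summed and their
sigmas combined in quadrature (`cell_flux_table()`).

Bulk particulate organic carbon (POC) fluxes come from brine-tube
collections split into equal volumetric fractions (default 1/8). Each
measured split mass is scaled by the split fraction and divided by the
collection period and the combined area of the duplicate tubes
($2 \times 0.0113 = 0.0226$ m$^2$); the uncertainty is the standard
deviation of the replicate splits. A single replicate is flagged rather
than assigned a spurious zero uncertainty.

Ratios built from these records (fold changes, percent-of-bulk,
solitary fractions) combine relative sigmas in quadrature. A
zero-count numerator would claim zero uncertainty under
$\sqrt{N}$; those ratios instead use the upper 68% Poisson bound on a
zero count (1.84 counts), and ratios above 1 — possible under sampling
noise when a gel and a bulk sample are compared — are flagged, not
clipped.

Depth-averaged fluxes are unweighted arithmetic means over the sampled
trap depths. The alternative — a trapezoidal integral divided by the
depth range — is available via `scheme = "trapezoid"`; the unweighted
mean is the default because it reproduces published deployment-to-
deployment fold changes computed from printed depth averages, and
because trap depths are design choices rather than a quadrature grid.

## Carbon conversion

Cell POC uses the spherical biovolume of a representative diameter
(default 45 µm, the midpoint of the measured 10–80 µm range) and a
power-law carbon–biovolume allometry $C = a V^b$ (pg C, µm$^3$). The
defaults, $a = 10^{-0.933}$, $b = 0.881$, are the widely used
diatom-specific regression; both are explicit arguments of
`cell_carbon_model()` because different taxa or size classes warrant
different coefficients, and no single pair should be treated as truth.
Unit conversion uses $1\,\mathrm{mmol\,C} = 12.011 \times 10^9$ pg C,
exposed as `PG_PER_MMOL_C`.

## Community comparison

Bray–Curtis dissimilarity, $\sum_k |x_k - y_k| / \sum_k (x_k + y_k)$,
is computed on untransformed absolute fluxes by default; relative-
abundance and fourth-root transforms are available behind the
`transform` argument since the choice is a genuine degree of freedom.
Group differences are tested by one-way PERMANOVA computed directly
from the dissimilarity matrix (the Anderson partition of squared
dissimilarities) with freely permuted sample labels, the conventional
choice when no blocking structure is declared; a `strata` argument
restricts permutations within blocks (e.g. depth) when that assumption
is wrong. The permutation p-value is $(1 + \#\{F^* \ge F\})/(1 + B)$
with $B = 9999$ by default. An exhaustive-enumeration variant
(`permanova_exact_p()`) exists for tiny designs and anchors the
Monte-Carlo p-values in the tests.

Ordination (`mds_embed()`) is classical metric scaling by
eigendecomposition, refined by Kruskal's nonmetric stress minimisation
when the configuration permits. It is visualisation only; no inference
is drawn from coordinates, so exact algorithmic parity with any
particular NMDS implementation is not a goal.

The similarity network links samples whose dissimilarity is *strictly*
below a threshold (default 0.25; ties at the threshold are excluded)
and partitions them into connected components. Components are labelled
deterministically by earliest deployment, then shallowest depth, of any
member, so repeated runs name clusters identically. Per-cluster mean
relative compositions pool taxa below a display floor (default 5%)
into `other`, preserving unit row sums.

## Covariation

Flux variables are min–max normalised to [0, 1] before PCA, and the
covariance (not correlation) matrix of the normalised columns is
eigendecomposed — normalising first and then correlating again would
double-standardise. Loadings carry a deterministic sign convention
(largest-magnitude element positive). Spearman correlation is the
Pearson correlation of mid-ranks, with a two-sided permutation p-value
(sidedness is the conservative default when no direction is
pre-specified); an asymptotic t approximation is available for speed.

## Sinking speeds

Two estimates bracket the kinematics. The geometric minimum,
`min_capture_speed()`, is simply tube height over collection period
(0.70 m over 1.7–5.9 d gives 0.12–0.41 m d$^{-1}$): any slower cell
cannot reach the gel within the deployment.

The translation inversion, `infer_translation_speed()`, treats the
decline in depth-integrated flux of one taxon between two deployments
as inventory that sank below the deepest observed depth. With
$\Delta I = \int \mathrm{early} - \int \mathrm{late}$ over the common
depth range, the translation depth $d$ solves

$$ \int_{z_{max}-d}^{z_{max}} \mathrm{early}(z)\, dz \;=\; \Delta I $$

by monotone bisection (tolerance $10^{-6}$ m), and the speed is
$d/\Delta t$. Bisection rather than a closed form because profiles are
arbitrary tabulated functions; integration is trapezoidal with linear
interpolation at interval endpoints. Where the profile must be
continued below the deepest trap, constant extrapolation at the deepest
observed flux is the default alternative, with a linear decay over a
configurable scale as a second option; both are flagged in the result.
The estimate is conservatively large: grazing, remineralisation and
patchiness all remove inventory without translation, so any such
unmodelled loss inflates $\Delta I$ and hence $d$ — a property the test
suite checks directly by adding simulated grazing. When the late
profile integrates to more than the early one, the estimate is 0 with a
`no_loss` flag instead of a negative speed.

## What the synthetic generator emulates

`generate_scenario()` produces the four input tables (trap metadata,
taxon counts with surveyed areas, bulk replicate split masses, detrital
particle-class POC fluxes) plus a noise-free truth sidecar. Its noise
structure mirrors the measurement model:

* **Counting**: counts are Poisson with mean
  flux × area × duration — the model under which the $\sqrt{N}$
  uncertainty is exact. Cells are assumed uniformly placed across the
  gel; within-gel clustering is not modelled, so real gels may show
  mild overdispersion the tests do not probe.
* **Platform variability**: each trap sample carries a lognormal
  multiplier, shared by all taxa of that sample (preserving
  composition), with a configurable coefficient of variation
  constrained to the observed 0.22–0.79 replicate-platform range
  (default 0.4).
* **Split replication**: bulk split masses get independent lognormal
  noise (default CV 10%, deliberately small so the split-propagation
  path is exercised without dominating the signal; no published
  replicate CV exists to match).
* **Depth structure**: exponential decay (e-folding 250 m), linear
  increase (to 3× the surface flux), or a Gaussian layer (default
  sigma 40 m) in one taxon that translates rigidly downward at a
  configured speed — the shape under which the rigid-translation
  inversion is exact, by construction.
* **Detrital coupling**: the small-detrital and aggregate POC fluxes
  are tied to the realised per-sample cell flux through a Gaussian
  copula whose correlation is set from the target Spearman rho
  ($r = 2\sin(\pi\rho_s/6)$). These coupled classes take their rank
  structure *only* from the copula: an earlier design also gave them a
  depth-decaying baseline, but the shared depth trend then induced
  rho ≈ 0.4 even at zero configured coupling, making the configured
  value unrecoverable. Uncoupled classes keep a depth-decaying
  baseline.

Everything is drawn in a fixed order from a single seed, so a
configuration is a complete recipe: identical config and seed give
byte-identical datasets, and the pipeline's provenance headers (package
version, config hash, seed) make any output file reproducible.

Passing parameter-recovery tests on these scenarios shows the
estimators are correct under the stated noise model; it does not show
the model captures everything in real gel data (within-gel clustering,
swimmer contamination, taxon misidentification, advection are all
outside it).

## Problem sizes used in the packaged checks

The test suite and the acceptance script run the translation-speed
recovery over 100 replicate datasets (23 depths, two taxa), the
PERMANOVA type-I-error check over 1,000 null simulations at $n = 12$
(two groups of six — with groups of four only 70 distinct label
partitions exist and the tied permutation distribution is visibly
conservative), the interval-calibration check over 1,200 Poisson
replicates at counts of 50–657, and the coupling recovery over 60
datasets. These sizes give Monte-Carlo errors comfortably inside the
tolerances asserted.

## Known limitations

* Magnification tiers are kept separate and summed; a taxon whose true
  detectability straddles tiers is not re-apportioned.
* The inversion attributes *all* integral loss to translation; it is an
  upper bound by design, not an unbiased estimator.
* The depth bounds of the loss integral use the common observed range;
  inventory entering the top of the window biases the inferred speed
  low if the profile is not negligible at the shallowest trap.
* PERMANOVA assumes exchangeable samples under free permutation;
  replicate platforms at one depth are mildly pseudo-replicated unless
  `strata` is used.
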