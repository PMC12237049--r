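#' @title Count and mass based flux calculations
#' @description Conversions from raw gel-layer cell counts and brine-tube
#'   carbon masses to fluxes, with Poisson counting uncertainty and
#'   replicate-split uncertainty propagated throughout.
#' @name flux-core
NULL

# pg C per mmol C (12.011 g/mol); exposed so carbon unit conversions are
# auditable rather than buried in formulas.
#' Conversion constant: picograms of carbon per millimole of carbon
#' @export
PG_PER_MMOL_C <- 12.011e9

# Upper 68% Poisson bound on a count of zero; used as the effective sigma
# (in counts) when a zero-count flux enters a ratio, since sqrt(0) = 0
# understates the uncertainty.
POISSON_ZERO_UPPER68 <- 1.84

#' Number flux from a gel-layer cell count
#'
#' Converts a cell count to a number flux by dividing by the gel surface
#' area surveyed at that detection tier and by the trap collection period.
#' The counting uncertainty is the Poisson sigma, sqrt(count), divided by
#' the same area and duration, so the relative uncertainty is
#' 1/sqrt(count).
#'
#' @param count Non-negative integer number of cells counted.
#' @param surveyed_area_m2 Gel surface area surveyed, m^2, > 0.
#' @param duration_d Trap collection period, days, > 0.
#' @return A [flux_record] in cells m^-2 d^-1 with `n_counted` set.
#' @examples
#' number_flux(100, 0.0005, 2)  # 1e5 +/- 1e4 cells m^-2 d^-1
#' @export
number_flux <- function(count, surveyed_area_m2, duration_d) {
  if (length(count) != 1L || is.na(count) || count < 0 ||
      abs(count - round(count)) > 1e-8) {
    stop("count must be a single non-negative integer")
  }
  if (surveyed_area_m2 <= 0) stop("surveyed_area_m2 must be > 0")
  if (duration_d <= 0) stop("duration_d must be > 0")
  denom <- surveyed_area_m2 * duration_d
  flux_record(value = count / denom,
              sigma = sqrt(count) / denom,
              units = "cells_m2_d",
              n_counted = count)
}

#' Bulk POC flux from replicate split masses
#'
#' Bulk collections are split into equal fractions by volume; each measured
#' split mass (already PIC-corrected upstream) is scaled back up by the
#' split fraction, then divided by the collection duration and the total
#' collection area. The uncertainty is propagated from the standard
#' deviation of the replicate splits; a single replicate yields sigma 0
#' with a `single_replicate` flag.
#'
#' @param split_masses Numeric vector of carbon masses per replicate split
#'   (e.g. umol C); at least one value.
#' @param split_fraction Fraction of the sample in each split, in (0, 1]
#'   (1/8 for the standard eight-way split).
#' @param duration_d Collection duration, days.
#' @param area_m2 Total collection area, m^2 (0.0226 for duplicate tubes).
#' @param units Units of the resulting flux; default `"umolC_m2_d"` when
#'   masses are in umol C.
#' @return A [flux_record].
#' @export
bulk_poc_flux <- function(split_masses, split_fraction, duration_d, area_m2,
                          units = "umolC_m2_d") {
  if (length(split_masses) < 1L) stop("need at least one replicate split mass")
  if (split_fraction <= 0 || split_fraction > 1) {
    stop("split_fraction must be in (0, 1]")
  }
  if (duration_d <= 0 || area_m2 <= 0) {
    stop("duration and area must be positive")
  }
  denom <- split_fraction * duration_d * area_m2
  fluxes <- split_masses / denom
  n <- length(fluxes)
  if (n == 1L) {
    return(flux_record(fluxes, 0, units = units, flags = "single_replicate"))
  }
  flux_record(mean(fluxes), stats::sd(fluxes), units = units)
}

#' Combined collection area of duplicate brine tubes
#'
#' @param tube_area_m2 Area of one cylindrical collection tube, m^2.
#' @param n_tubes Number of tubes combined (2 for the duplicate brine
#'   tubes).
#' @return Combined area in m^2.
#' @export
combined_tube_area <- function(tube_area_m2 = 0.0113, n_tubes = 2L) {
  stopifnot(tube_area_m2 > 0, n_tubes >= 1)
  tube_area_m2 * n_tubes
}

#' Depth-averaged flux over a profile
#'
#' The depth average is the unweighted arithmetic mean of the fluxes at
#' the sampled trap depths, with sigmas combined in quadrature. A
#' depth-weighted alternative (trapezoidal integral divided by the depth
#' range) is available via `scheme = "trapezoid"` for unevenly spaced
#' profiles.
#'
#' @param fluxes List of [flux_record]s (same units), ordered by depth.
#' @param depths_m Optional numeric depths; required for
#'   `scheme = "trapezoid"`.
#' @param scheme `"mean"` (default) or `"trapezoid"`.
#' @return A [flux_record] of the same units.
#' @export
depth_average_flux <- function(fluxes, depths_m = NULL, scheme = c("mean", "trapezoid")) {
  scheme <- match.arg(scheme)
  if (length(fluxes) < 1L) stop("empty flux profile")
  if (is_flux_record(fluxes)) fluxes <- list(fluxes)
  for (f in fluxes[-1]) check_same_units(fluxes[[1]], f)
  vals <- vapply(fluxes, function(f) f$value, numeric(1))
  sigs <- vapply(fluxes, function(f) f$sigma, numeric(1))
  n <- length(vals)
  if (scheme == "mean") {
    return(flux_record(mean(vals), sqrt(sum(sigs^2)) / n,
                       units = fluxes[[1]]$units))
  }
  if (is.null(depths_m) || length(depths_m) != n) {
    stop("trapezoid scheme needs one depth per flux")
  }
  if (n == 1L) return(fluxes[[1]])
  if (any(diff(depths_m) <= 0)) stop("depths must be strictly increasing")
  rng <- diff(range(depths_m))
  w <- trapezoid_weights(depths_m) / rng
  flux_record(sum(w * vals), sqrt(sum((w * sigs)^2)),
              units = fluxes[[1]]$units)
}

# Trapezoidal quadrature weights for nodes z (sum(w * f) == trapz integral).
trapezoid_weights <- function(z) {
  n <- length(z)
  w <- numeric(n)
  dz <- diff(z)
  w[1] <- dz[1] / 2
  w[n] <- dz[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dz[-(n - 1)] + dz[-1]) / 2
  w
}

#' Fold change between two fluxes
#'
#' Ratio of a later to an earlier flux; relative uncertainties are added
#' in quadrature.
#'
#' @param later,earlier [flux_record]s in the same units;
#'   `earlier$value > 0`.
#' @return A [flux_record] with units `"ratio"`.
#' @examples
#' fold_change(flux_record(1.26e6, 0, "cells_m2_d"),
#'             flux_record(0.42e6, 0, "cells_m2_d"))  # 3-fold
#' @export
fold_change <- function(later, earlier) {
  stopifnot(is_flux_record(later), is_flux_record(earlier))
  check_same_units(later, earlier)
  if (earlier$value <= 0) stop("earlier flux must be positive for a fold change")
  ratio <- later$value / earlier$value
  if (ratio == 0) return(flux_record(0, 0, units = "ratio"))
  rel <- sqrt(relative_sigma(later)^2 + relative_sigma(earlier)^2)
  flux_record(ratio, ratio * rel, units = "ratio")
}

# Relative sigma with the zero-count guard: a count-derived record with
# zero counts uses the upper 68% Poisson bound (1.84 counts) so that
# ratios built from it do not claim zero uncertainty.
relative_sigma <- function(f) {
  if (f$value == 0) {
    if (!is.na(f$n_counted) && f$n_counted == 0L) return(Inf)
    return(0)
  }
  if (!is.na(f$n_counted) && f$n_counted == 0L) return(Inf)
  f$sigma / f$value
}

#' Volume of a sphere from its diameter
#'
#' @param diameter_um Cell diameter in micrometers, > 0.
#' @return Volume in cubic micrometers, (pi/6) d^3.
#' @export
sphere_volume <- function(diameter_um) {
  if (any(diameter_um <= 0)) stop("diameter must be positive")
  (pi / 6) * diameter_um^3
}

#' Allometric cell-carbon model
#'
#' Carbon per cell follows the power law `a * V^b` with `V` the cell
#' biovolume in um^3 and carbon in pg C. Defaults are the diatom
#' carbon-biovolume regression widely used for large diatoms
#' (log10 pgC = -0.933 + 0.881 log10 V); both coefficients are
#' configuration, not hard-coded truth.
#'
#' @param diameter_um Representative cell diameter, um; must lie in the
#'   measured 10-80 um range (midpoint default 45).
#' @param allometric_a Coefficient a, pg C per um^3^b, > 0.
#' @param allometric_b Exponent b, in (0, 1].
#' @return An object of class `cell_carbon_model`.
#' @export
cell_carbon_model <- function(diameter_um = 45,
                              allometric_a = 10^-0.933,
                              allometric_b = 0.881) {
  if (diameter_um < 10 || diameter_um > 80) {
    stop("diameter_um must lie within the measured 10-80 um range")
  }
  if (allometric_a <= 0) stop("allometric_a must be > 0")
  if (allometric_b <= 0 || allometric_b > 1) {
    stop("allometric_b must be in (0, 1]")
  }
  structure(list(diameter_um = diameter_um,
                 allometric_a = allometric_a,
                 allometric_b = allometric_b),
            class = "cell_carbon_model")
}

#' Carbon content of a cell from its biovolume
#'
#' @param volume_um3 Cell biovolume, um^3, > 0.
#' @param model A [cell_carbon_model].
#' @return Carbon per cell in pg C.
#' @export
cell_carbon <- function(volume_um3, model = cell_carbon_model()) {
  stopifnot(inherits(model, "cell_carbon_model"))
  if (any(volume_um3 <= 0)) stop("volume must be positive")
  model$allometric_a * volume_um3^model$allometric_b
}

#' Cell carbon flux as a percentage of bulk POC flux
#'
#' Multiplies a cell number flux by the per-cell carbon content, converts
#' pg C to the bulk flux's carbon units, and expresses the result as a
#' percentage of the bulk POC flux. Uncertainty combines the cell
#' counting uncertainty and the bulk POC replicate uncertainty in
#' quadrature (relative sigmas).
#'
#' @param cell_flux [flux_record] in cells m^-2 d^-1.
#' @param carbon_per_cell_pg Carbon per cell, pg C.
#' @param bulk_poc [flux_record] in `"mmolC_m2_d"` or `"umolC_m2_d"`;
#'   value > 0.
#' @param pg_per_mmol Conversion constant; default [PG_PER_MMOL_C].
#' @return A [flux_record] with units `"percent"`.
#' @export
percent_of_bulk_poc <- function(cell_flux, carbon_per_cell_pg, bulk_poc,
                                pg_per_mmol = PG_PER_MMOL_C) {
  stopifnot(is_flux_record(cell_flux), is_flux_record(bulk_poc))
  if (cell_flux$units != "cells_m2_d") {
    stop("cell_flux must be a number flux in cells m^-2 d^-1")
  }
  if (!bulk_poc$units %in% c("mmolC_m2_d", "umolC_m2_d")) {
    stop("bulk_poc must be a carbon flux")
  }
  if (bulk_poc$value <= 0) stop("bulk POC flux must be positive")
  mmol_factor <- if (bulk_poc$units == "mmolC_m2_d") 1 else 1000
  cell_c_mmol <- cell_flux$value * carbon_per_cell_pg / pg_per_mmol * mmol_factor
  pct <- 100 * cell_c_mmol / bulk_poc$value
  if (cell_flux$value == 0) {
    # zero-count numerator: report the upper 68% Poisson-bound sigma
    zero_sig <- if (!is.na(cell_flux$n_counted) && cell_flux$n_counted == 0L &&
                    !is.na(guess_count_scale(cell_flux))) {
      POISSON_ZERO_UPPER68 * guess_count_scale(cell_flux)
    } else 0
    zero_c <- zero_sig * carbon_per_cell_pg / pg_per_mmol * mmol_factor
    return(flux_record(0, 100 * zero_c / bulk_poc$value, units = "percent",
                       flags = "zero_count_numerator"))
  }
  rel <- sqrt(relative_sigma(cell_flux)^2 + relative_sigma(bulk_poc)^2)
  flux_record(pct, pct * rel, units = "percent")
}

# Flux-per-count scale (1/(area*duration)) recovered from a count-derived
# record; NA when not count-derived or count is zero with no sigma trace.
guess_count_scale <- function(f) {
  if (is.na(f$n_counted)) return(NA_real_)
  if (f$n_counted > 0L) return(f$value / f$n_counted)
  NA_real_
}

#' Fraction of bulk cell flux accounted for by solitary gel-captured cells
#'
#' Ratio of the number flux detected as solitary individuals in the gel
#' layer to the number flux of the same taxon in a co-deployed
#' bulk-collected sample. A ratio of 1 means the entire sinking population
#' was solitary; ratios above 1 (sampling noise) are allowed but flagged.
#' Counting uncertainty is propagated from both counts; a zero gel count
#' uses the upper 68% Poisson bound (1.84 counts) for its sigma.
#'
#' @param gel_flux,bulk_flux [flux_record]s in cells m^-2 d^-1 from
#'   co-deployed samples (same depth, overlapping interval);
#'   `bulk_flux$value > 0`.
#' @return A [flux_record] with units `"ratio"`.
#' @export
solitary_fraction <- function(gel_flux, bulk_flux) {
  stopifnot(is_flux_record(gel_flux), is_flux_record(bulk_flux))
  check_same_units(gel_flux, bulk_flux)
  if (bulk_flux$value <= 0) stop("bulk flux must be positive")
  ratio <- gel_flux$value / bulk_flux$value
  flags <- character()
  if (ratio > 1) flags <- "ratio_gt_1"
  if (gel_flux$value == 0) {
    scale <- guess_count_scale_zero(gel_flux, bulk_flux)
    sig <- if (is.na(scale)) 0 else POISSON_ZERO_UPPER68 * scale / bulk_flux$value
    return(flux_record(0, sig, units = "ratio",
                       flags = c(flags, "zero_count_numerator")))
  }
  rel <- sqrt(relative_sigma(gel_flux)^2 + relative_sigma(bulk_flux)^2)
  flux_record(ratio, ratio * rel, units = "ratio", flags = flags)
}

# For a zero-count gel record we cannot recover flux-per-count from the
# record itself; fall back on the bulk record's scale when available.
guess_count_scale_zero <- function(zero_rec, other_rec) {
  s <- guess_count_scale(other_rec)
  if (!is.na(s)) return(s)
  NA_real_
}
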