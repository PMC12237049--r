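test_that("number flux divides counts by surveyed area and duration with Poisson sigma", {
  z <- number_flux(0, 0.001, 2)
  expect_equal(z$value, 0)
  expect_equal(z$sigma, 0)

  f <- number_flux(100, 0.0005, 2)
  expect_equal(f$value, 1e5)
  expect_equal(f$sigma, 1e4)
  expect_equal(f$n_counted, 100L)

  # relative counting uncertainty is 1/sqrt(count) regardless of area/duration
  for (case in list(c(657, 1e-3, 3), c(657, 0.0113, 1.8), c(301, 2e-4, 6))) {
    f <- number_flux(case[1], case[2], case[3])
    expect_equal(f$sigma / f$value, 1 / sqrt(case[1]))
  }
  expect_equal(number_flux(657, 1, 1)$sigma / number_flux(657, 1, 1)$value,
               0.039, tolerance = 0.01)

  expect_error(number_flux(10, 0, 1), "area")
  expect_error(number_flux(10, 1, 0), "duration")
  expect_error(number_flux(-1, 1, 1))
})

test_that("flux linearity: scaling count and area together leaves value fixed, sigma drops as 1/sqrt(k)", {
  base <- number_flux(50, 0.002, 3)
  for (k in c(2, 5, 10)) {
    scaled <- number_flux(50 * k, 0.002 * k, 3)
    expect_equal(scaled$value, base$value)
    expect_equal(scaled$sigma, base$sigma / sqrt(k))
  }
})

test_that("bulk POC flux rescales split masses and propagates replicate spread", {
  one <- bulk_poc_flux(2.5, split_fraction = 1, duration_d = 1, area_m2 = 1)
  expect_equal(one$value, 2.5)
  expect_equal(one$sigma, 0)
  expect_true("single_replicate" %in% one$flags)

  # three equal 1 umol splits of an 8-way split over 2 d on 0.0226 m^2
  f <- bulk_poc_flux(c(1, 1, 1), 1 / 8, 2, 0.0226)
  expect_equal(f$value, 1 / 0.125 / 2 / 0.0226, tolerance = 1e-12)
  expect_equal(f$value, 177.0, tolerance = 1e-3)
  expect_equal(f$sigma, 0)

  spread <- bulk_poc_flux(c(0.9, 1.0, 1.1), 1 / 8, 2, 0.0226)
  expect_equal(spread$value, 177.0, tolerance = 1e-3)
  expect_equal(spread$sigma, sd(c(0.9, 1.0, 1.1)) / 0.125 / 2 / 0.0226)

  expect_error(bulk_poc_flux(numeric(0), 0.125, 1, 1), "replicate")
  expect_error(bulk_poc_flux(1, 0, 1, 1), "split_fraction")
})

test_that("duplicate brine tubes combine to the documented collection area", {
  expect_equal(combined_tube_area(0.0113, 2), 0.0226)
  expect_equal(combined_tube_area(), 0.0226)
})

test_that("depth averaging is the arithmetic mean with quadrature sigma; trapezoid scheme available", {
  single <- flux_record(5e5, 1e4, "cells_m2_d")
  expect_equal(depth_average_flux(list(single))$value, 5e5)

  prof <- lapply(c(1e6, 2e6, 3e6), flux_record, sigma = 0,
                 units = "cells_m2_d")
  expect_equal(depth_average_flux(prof)$value, 2e6)

  withsig <- lapply(1:3, function(i) flux_record(i, 0.3, "cells_m2_d"))
  expect_equal(depth_average_flux(withsig)$sigma, sqrt(3 * 0.09) / 3)

  # trapezoid scheme equals the mean on an evenly spaced linear profile
  tz <- depth_average_flux(prof, depths_m = c(100, 200, 300),
                           scheme = "trapezoid")
  expect_equal(tz$value, 2e6)
  expect_error(depth_average_flux(list()), "empty")
})

test_that("fold change reproduces printed deployment-to-deployment increases", {
  fr <- function(v) flux_record(v, 0, "cells_m2_d")
  expect_equal(fold_change(fr(1.26e6), fr(0.42e6))$value, 3.0)
  expect_equal(round(fold_change(fr(2.23e6), fr(1.26e6))$value, 1), 1.8)
  expect_equal(round(fold_change(fr(0.23e6), fr(0.055e6))$value, 1), 4.2)
  expect_equal(fold_change(fr(7), fr(7))$value, 1.0)
  expect_error(fold_change(fr(1), fr(0)), "positive")

  # relative sigmas add in quadrature
  a <- flux_record(200, 20, "cells_m2_d")
  b <- flux_record(100, 5, "cells_m2_d")
  fc <- fold_change(a, b)
  expect_equal(fc$sigma, 2 * sqrt(0.1^2 + 0.05^2))
})

test_that("sphere volume and allometric cell carbon behave as closed forms", {
  expect_equal(sphere_volume(1), pi / 6)
  expect_equal(sphere_volume(45), 47712.9, tolerance = 1e-5)
  d0 <- 17.3
  expect_equal(sphere_volume(2 * d0), 8 * sphere_volume(d0))
  expect_error(sphere_volume(0))

  m <- cell_carbon_model(45, allometric_a = 0.2, allometric_b = 0.9)
  expect_equal(cell_carbon(1, m), 0.2)
  lin <- cell_carbon_model(45, allometric_a = 0.1, allometric_b = 1)
  expect_equal(cell_carbon(c(10, 20), lin), c(1, 2))
  # ratio identity independent of the coefficient a
  v1 <- 5000; v2 <- 800
  expect_equal(cell_carbon(v1, m) / cell_carbon(v2, m), (v1 / v2)^0.9)
  expect_error(cell_carbon_model(diameter_um = 5), "10-80")
  expect_error(cell_carbon_model(allometric_b = 1.2), "0, 1")
})

test_that("percent of bulk POC converts units and propagates both uncertainties", {
  bulk <- flux_record(10, 0, "mmolC_m2_d")
  # cell carbon flux engineered to equal the bulk flux exactly
  pg_per_cell <- 100
  cells <- flux_record(10 * PG_PER_MMOL_C / pg_per_cell, 0, "cells_m2_d")
  expect_equal(percent_of_bulk_poc(cells, pg_per_cell, bulk)$value, 100)

  zero <- number_flux(0, 1e-3, 2)
  expect_equal(percent_of_bulk_poc(zero, pg_per_cell, bulk)$value, 0)

  # quadrature of relative sigmas
  cf <- flux_record(1e6, 1e5, "cells_m2_d", n_counted = 100L)
  bk <- flux_record(5, 1, "mmolC_m2_d")
  pct <- percent_of_bulk_poc(cf, 50, bk)
  expect_equal(pct$sigma / pct$value, sqrt(0.1^2 + 0.2^2))
  expect_error(percent_of_bulk_poc(cf, 50, flux_record(0, 0, "mmolC_m2_d")),
               "positive")
})

test_that("solitary fraction flags ratios above one and widens zero-count sigma", {
  gel <- number_flux(50, 1e-3, 2)
  bulk <- number_flux(50, 1e-3, 2)
  expect_equal(solitary_fraction(gel, bulk)$value, 1.0)

  none <- solitary_fraction(number_flux(0, 1e-3, 2), bulk)
  expect_equal(none$value, 0)
  expect_gt(none$sigma, 0)  # upper 68% Poisson bound, not sqrt(0)

  over <- solitary_fraction(number_flux(80, 1e-3, 2), bulk)
  expect_true("ratio_gt_1" %in% over$flags)
  expect_error(solitary_fraction(gel, flux_record(0, 0, "cells_m2_d")),
               "positive")
})

test_that("cell-number and carbon fluxes refuse to combine", {
  a <- flux_record(10, 1, "cells_m2_d")
  b <- flux_record(10, 1, "mmolC_m2_d")
  expect_error(fold_change(a, b), "units differ")
  expect_error(solitary_fraction(a, b), "units differ")
  expect_error(flux_record(-1, 0, "cells_m2_d"), "non-negative")
})
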