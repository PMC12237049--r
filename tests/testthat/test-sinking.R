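test_that("minimum capture speed is tube height over collection period", {
  expect_equal(round(min_capture_speed(0.70, 5.9), 1), 0.1)
  expect_equal(round(min_capture_speed(0.70, 1.7), 1), 0.4)
  expect_equal(min_capture_speed(0.35, 0.35), 1.0)
  expect_error(min_capture_speed(-1, 2), "positive")
  expect_error(min_capture_speed(0.7, 0), "positive")
})

test_that("depth-integrated flux matches closed forms", {
  # constant flux -> rectangle
  p <- flux_profile(c(100, 200, 300, 400), rep(5e5, 4))
  expect_equal(depth_integrated_flux(p, 150, 350), 5e5 * 200)
  # triangular profile with nodes on the vertices -> closed-form area
  tri <- flux_profile(c(100, 300, 500), c(0, 1e6, 0))
  expect_equal(depth_integrated_flux(tri, 100, 500), 0.5 * 400 * 1e6,
               tolerance = 1e-12)
  # endpoint interpolation between nodes
  expect_equal(depth_integrated_flux(tri, 200, 300),
               0.5 * (5e5 + 1e6) * 100, tolerance = 1e-12)
  # zero flux everywhere
  z <- flux_profile(c(50, 150), c(0, 0))
  expect_equal(depth_integrated_flux(z, 50, 150), 0)
  expect_error(depth_integrated_flux(p, 50, 350), "support")
  expect_error(depth_integrated_flux(p, 300, 200), "less than")
})

test_that("flux profile construction enforces ordering and signs", {
  expect_error(flux_profile(c(200, 100), c(1, 2)), "increasing")
  expect_error(flux_profile(c(-5, 100), c(1, 2)), "positive")
  expect_error(flux_profile(c(100, 200), c(1, -2)), "non-negative")
})

test_that("identical profiles yield zero translation speed with a no-loss flag", {
  p <- flux_profile(seq(100, 500, 50), dnorm(seq(100, 500, 50), 300, 80))
  est <- infer_translation_speed(p, p, delta_t_d = 7)
  expect_equal(est$speed_m_d, 0)
  expect_true(est$no_loss)
})

test_that("rectangle translation oracle: 70 m exit over 7 d gives 10 m/d", {
  # early: rectangle of height F on [400, 500] (steep linear edges)
  zs <- c(seq(50, 399, by = 1), seq(400, 500, by = 1))
  F0 <- 1e4
  early_f <- ifelse(zs >= 400, F0, 0)
  # late: same rectangle shifted down 70 m; only [470, 500] remains observed
  late_f <- ifelse(zs >= 470, F0, 0)
  early <- flux_profile(zs, early_f)
  late <- flux_profile(zs, late_f)
  est <- infer_translation_speed(early, late, delta_t_d = 7)
  expect_equal(est$sink_depth_m, 70, tolerance = 1e-3)
  expect_equal(est$speed_m_d, 10, tolerance = 1e-3)
  expect_equal(est$speed_m_d, est$sink_depth_m / est$delta_t_d)
})

test_that("construct-then-invert recovers any translation depth to the bisection tolerance", {
  set.seed(20)
  zs <- seq(100, 500, by = 5)
  for (i in 1:10) {
    f <- rgamma(length(zs), 2, 1e-5) + 1e3
    early <- flux_profile(zs, f)
    d_star <- runif(1, 5, 390)
    # build a late profile whose integral deficit equals the bottom-d* integral
    dI <- depth_integrated_flux(early, 500 - d_star, 500)
    I_early <- depth_integrated_flux(early, 100, 500)
    late <- flux_profile(zs, f * (1 - dI / I_early))
    est <- infer_translation_speed(early, late, delta_t_d = 7)
    expect_equal(est$sink_depth_m, d_star, tolerance = 1e-5)
  }
})

test_that("larger integral loss never yields a smaller translation depth", {
  zs <- seq(100, 500, by = 10)
  f <- dnorm(zs, 420, 50) * 1e8
  early <- flux_profile(zs, f)
  depths <- vapply(seq(0.95, 0.3, by = -0.05), function(scl) {
    late <- flux_profile(zs, f * scl)
    infer_translation_speed(early, late, delta_t_d = 7)$sink_depth_m
  }, numeric(1))
  expect_true(all(diff(depths) >= -1e-9))
})

test_that("non-translation losses only increase the inferred speed (conservative bound)", {
  zs <- seq(100, 500, by = 5)
  f <- dnorm(zs, 430, 40) * 1e8
  early <- flux_profile(zs, f)
  # true translation by 30 m
  shifted <- approx(zs, f, xout = zs - 30, rule = 2)$y
  shifted[zs - 30 < min(zs)] <- 0
  base <- infer_translation_speed(early, flux_profile(zs, shifted), 7)
  for (graze in c(0.05, 0.15, 0.3)) {
    eaten <- infer_translation_speed(
      early, flux_profile(zs, shifted * (1 - graze)), 7)
    expect_gte(eaten$speed_m_d, base$speed_m_d)
  }
})

test_that("loss larger than the whole early inventory is rejected", {
  zs <- seq(100, 500, by = 50)
  early <- flux_profile(zs, rep(1e5, length(zs)))
  late <- flux_profile(zs, rep(0, length(zs)))
  # late all-zero: loss equals the whole inventory, still invertible (d = range)
  est <- infer_translation_speed(early, late, 7)
  expect_equal(est$sink_depth_m, 400, tolerance = 1e-5)
})

test_that("noise-free generator layer translation is recovered within 5%", {
  cfg <- layer_config(speed = 6.6)
  ds <- generate_scenario(cfg)
  early <- truth_profile(ds, "Fragilariopsis", 2)
  late <- truth_profile(ds, "Fragilariopsis", 3)
  est <- infer_translation_speed(early, late, delta_t_d = 7)
  expect_equal(est$speed_m_d, 6.6, tolerance = 0.05)
})

test_that("median recovered speed across noisy replicates stays within 15% of truth", {
  speeds <- vapply(1:40, function(s) {
    ds <- generate_scenario(layer_config(seed = 5000 + s, speed = 6.6,
                                         n_platforms = 2L))
    ft <- cell_flux_table(ds$counts)
    cfg_a <- analysis_config(sinking_taxon = "Fragilariopsis",
                             sinking_deployments = c(2L, 3L), delta_t_d = 7)
    rec <- gelflux:::pipeline_sinking(ft, ds$trap_samples, cfg_a)
    rec$speed_m_d
  }, numeric(1))
  expect_equal(median(speeds), 6.6, tolerance = 0.15)
})
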