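#' @title Sinking-speed estimation from trap geometry and flux-profile
#'   translation
#' @description Two complementary speed estimates: the geometric minimum
#'   speed a cell needs to reach the gel layer at the bottom of a trap
#'   tube within the collection period, and an inversion of the loss in
#'   depth-integrated cell flux between consecutive deployments under the
#'   assumption that the profile translates rigidly downward.
#' @name sinking
NULL

#' Minimum sinking speed required for gel capture
#'
#' A cell entering the top of a collection tube must traverse the tube
#' height within the collection period to be captured in the gel layer at
#' its base, so the minimum speed is height / duration.
#'
#' @param tube_height_m Height of the collection tube, m (default 0.70).
#' @param duration_d Collection period, days.
#' @return Minimum sinking speed in m d^-1.
#' @examples
#' min_capture_speed(0.70, 5.9)  # ~0.12 m/d
#' min_capture_speed(0.70, 1.7)  # ~0.41 m/d
#' @export
min_capture_speed <- function(tube_height_m = 0.70, duration_d) {
  if (tube_height_m <= 0) stop("tube height must be positive")
  if (any(duration_d <= 0)) stop("duration must be positive")
  tube_height_m / duration_d
}

#' Flux profile of one taxon across trap depths
#'
#' @param depths_m Strictly increasing positive depths, m.
#' @param fluxes Non-negative fluxes, cells m^-2 d^-1, one per depth.
#' @param sigmas Optional 1-sigma uncertainties (default 0).
#' @param taxon,deployment Optional labels.
#' @return Object of class `flux_profile`.
#' @export
flux_profile <- function(depths_m, fluxes, sigmas = NULL,
                         taxon = NA_character_, deployment = NA_integer_) {
  if (length(depths_m) != length(fluxes)) stop("depths and fluxes differ in length")
  if (any(depths_m <= 0)) stop("depths must be positive")
  if (any(diff(depths_m) <= 0)) stop("depths must be strictly increasing")
  if (any(fluxes < 0)) stop("fluxes must be non-negative")
  if (is.null(sigmas)) sigmas <- rep(0, length(fluxes))
  structure(list(depths_m = as.numeric(depths_m),
                 fluxes = as.numeric(fluxes),
                 sigmas = as.numeric(sigmas),
                 taxon = taxon, deployment = deployment),
            class = "flux_profile")
}

#' Depth-integrated flux over a depth range
#'
#' Trapezoidal integration of the tabulated flux profile between `z_lo`
#' and `z_hi`, with linear interpolation of the flux at interval
#' endpoints that fall between nodes. The integral of a flux
#' (cells m^-2 d^-1) over depth (m) is a per-unit-area column inventory
#' flux, cells m^-1 d^-1.
#'
#' @param profile A [flux_profile] with at least 2 depths.
#' @param z_lo,z_hi Integration bounds, `z_lo < z_hi`, both within the
#'   profile's depth support.
#' @return The integral, cells m^-1 d^-1.
#' @export
depth_integrated_flux <- function(profile, z_lo = min(profile$depths_m),
                                  z_hi = max(profile$depths_m)) {
  stopifnot(inherits(profile, "flux_profile"))
  z <- profile$depths_m
  f <- profile$fluxes
  if (length(z) < 2) stop("integration needs at least 2 depths")
  if (z_lo >= z_hi) stop("z_lo must be less than z_hi")
  if (z_lo < min(z) - 1e-9 || z_hi > max(z) + 1e-9) {
    stop("integration range outside the profile's depth support")
  }
  trapz_interp(z, f, z_lo, z_hi)
}

# Trapezoid integral of the piecewise-linear interpolant of (z, f) over
# [a, b]; nodes outside [a, b] are clipped with linear interpolation.
trapz_interp <- function(z, f, a, b) {
  a <- max(a, min(z)); b <- min(b, max(z))
  if (b <= a) return(0)
  inner <- z[z > a & z < b]
  zz <- c(a, inner, b)
  ff <- stats::approx(z, f, xout = zz, rule = 2)$y
  sum(diff(zz) * (ff[-length(ff)] + ff[-1]) / 2)
}

#' Infer a rigid-translation sinking speed from two flux profiles
#'
#' Treats the decline in depth-integrated cell flux between an earlier
#' and a later deployment as cells that sank out below the deepest
#' observed depth. Steps: (1) the lost inventory
#' `delta_I = integral(early) - integral(late)` over the common observed
#' depth range; (2) assuming the early profile translates rigidly
#' downward with no other losses, the lost inventory equals the early
#' profile's integral over its bottom `d` metres, so `d` solves
#' `integral_{z_max - d}^{z_max} early(z) dz = delta_I` by monotone
#' bisection; (3) `speed = d / delta_t`. Because grazing,
#' remineralisation and patchiness would also remove inventory, the
#' estimate is conservatively large.
#'
#' Two variants of the bottom-`d` integral are reported: `"observed"`
#' restricts `d` to the observed depth range, while `"extrapolated"`
#' continues the profile below the deepest node at the deepest observed
#' flux (constant extrapolation, flagged) or with a linear decay to zero
#' over `decay_scale_m`.
#'
#' @param profile_early,profile_late [flux_profile]s sharing depth
#'   support.
#' @param delta_t_d Time between the deployments, days (default 7).
#' @param z_max Bottom of the observational region, m; default the
#'   deepest common node.
#' @param extrapolation `"observed"` (default), `"constant"`, or
#'   `"linear_decay"`.
#' @param decay_scale_m Depth scale over which the extrapolated flux
#'   decays linearly to zero (only for `"linear_decay"`; default 100).
#' @param tol_m Bisection tolerance on `d`, m (default 1e-6).
#' @return Object of class `sinking_speed_estimate`: `sink_depth_m`,
#'   `delta_t_d`, `speed_m_d` (= depth/time exactly), `delta_I`,
#'   `no_loss` flag, `assumptions` character vector.
#' @export
infer_translation_speed <- function(profile_early, profile_late,
                                    delta_t_d = 7, z_max = NULL,
                                    extrapolation = c("observed", "constant",
                                                      "linear_decay"),
                                    decay_scale_m = 100, tol_m = 1e-6) {
  extrapolation <- match.arg(extrapolation)
  stopifnot(inherits(profile_early, "flux_profile"),
            inherits(profile_late, "flux_profile"))
  if (delta_t_d <= 0) stop("delta_t_d must be positive")
  z_lo <- max(min(profile_early$depths_m), min(profile_late$depths_m))
  z_hi <- min(max(profile_early$depths_m), max(profile_late$depths_m))
  if (z_hi <= z_lo) stop("profiles share no depth support")
  if (is.null(z_max)) z_max <- z_hi
  I_early <- depth_integrated_flux(profile_early, z_lo, z_hi)
  I_late <- depth_integrated_flux(profile_late, z_lo, z_hi)
  delta_I <- I_early - I_late
  assumptions <- c("rigid_translation", "no_grazing_loss",
                   "no_remineralization_loss", "conservatively_large")
  if (delta_I <= 0) {
    return(new_speed_estimate(0, delta_t_d, delta_I,
                              no_loss = TRUE, assumptions = assumptions))
  }
  bottom_integral <- make_bottom_integral(profile_early, z_lo, z_max,
                                          extrapolation, decay_scale_m)
  d_max <- bottom_integral$d_max
  total <- bottom_integral$fn(d_max)
  if (delta_I > total * (1 + 1e-9)) {
    stop("integrated loss exceeds the total early inventory; ",
         "loss unexplainable by rigid translation")
  }
  d <- bisect_monotone(bottom_integral$fn, delta_I, 0, d_max, tol_m)
  if (extrapolation != "observed") {
    assumptions <- c(assumptions, paste0("extrapolation_", extrapolation))
  }
  new_speed_estimate(d, delta_t_d, delta_I, no_loss = FALSE,
                     assumptions = assumptions)
}

# Returns fn(d) = integral of the early profile over its bottom d metres
# (from z_max - d up to z_max, possibly into the extrapolated tail), a
# nondecreasing function of d, plus the largest admissible d.
make_bottom_integral <- function(profile, z_lo, z_max, extrapolation,
                                 decay_scale_m) {
  z <- profile$depths_m
  f <- profile$fluxes
  z_obs_max <- max(z)
  f_deep <- f[length(f)]
  if (extrapolation == "observed") {
    z_max <- min(z_max, z_obs_max)
    fn <- function(d) trapz_interp(z, f, z_max - d, z_max)
    return(list(fn = fn, d_max = z_max - z_lo))
  }
  # extend nodes below the deepest observation
  if (extrapolation == "constant") {
    z_ext <- c(z, max(z_max, z_obs_max) + 1)
    f_ext <- c(f, f_deep)
  } else {  # linear decay to zero over decay_scale_m
    z_ext <- c(z, z_obs_max + decay_scale_m)
    f_ext <- c(f, 0)
  }
  fn <- function(d) trapz_interp(z_ext, f_ext, z_max - d, z_max)
  list(fn = fn, d_max = z_max - z_lo)
}

# Bisection for the smallest d with fn(d) >= target; fn nondecreasing.
bisect_monotone <- function(fn, target, lo, hi, tol) {
  if (fn(hi) < target) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fn(mid) >= target) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

new_speed_estimate <- function(sink_depth_m, delta_t_d, delta_I,
                               no_loss, assumptions) {
  structure(list(sink_depth_m = sink_depth_m,
                 delta_t_d = delta_t_d,
                 speed_m_d = sink_depth_m / delta_t_d,
                 delta_I = delta_I,
                 no_loss = no_loss,
                 assumptions = assumptions),
            class = "sinking_speed_estimate")
}

#' @export
print.sinking_speed_estimate <- function(x, ...) {
  cat(sprintf("<sinking_speed_estimate> %.3g m/d (depth %.3g m over %.3g d)%s\n",
              x$speed_m_d, x$sink_depth_m, x$delta_t_d,
              if (x$no_loss) " [no net loss]" else ""))
  invisible(x)
}
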