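#' Flux record with symmetric 1-sigma uncertainty
#'
#' A `flux_record` is the package's atomic result type: a non-negative flux
#' value, its symmetric 1-sigma uncertainty, the units the value is
#' expressed in, and (for count-derived fluxes) the raw number of cells
#' counted. Units are carried explicitly so that cell-number and
#' carbon-mass fluxes can never be combined by accident.
#'
#' @param value Flux value, must be >= 0 unless `allow_negative`.
#' @param sigma Symmetric 1-sigma uncertainty, >= 0.
#' @param units One of `"cells_m2_d"` (cells m^-2 d^-1), `"mmolC_m2_d"`
#'   (mmol C m^-2 d^-1), `"umolC_m2_d"`, `"percent"`, `"ratio"`.
#' @param n_counted Integer count the record derives from, or `NA` when the
#'   record is not count-derived.
#' @param flags Character vector of quality flags (e.g.
#'   `"single_replicate"`, `"ratio_gt_1"`).
#' @param allow_negative Permit negative values (differences); default FALSE.
#' @return An object of class `flux_record`.
#' @export
flux_record <- function(value, sigma, units, n_counted = NA_integer_,
                        flags = character(), allow_negative = FALSE) {
  stopifnot(is.numeric(value), length(value) == 1L,
            is.numeric(sigma), length(sigma) == 1L)
  if (!allow_negative && value < 0) {
    stop("flux_record: value must be non-negative, got ", value)
  }
  if (sigma < 0) stop("flux_record: sigma must be non-negative, got ", sigma)
  units <- match.arg(units,
                     c("cells_m2_d", "mmolC_m2_d", "umolC_m2_d",
                       "percent", "ratio", "pgC_m2_d"))
  structure(
    list(value = as.numeric(value), sigma = as.numeric(sigma),
         units = units,
         n_counted = if (is.na(n_counted)) NA_integer_ else as.integer(n_counted),
         flags = flags),
    class = "flux_record"
  )
}

#' @export
print.flux_record <- function(x, ...) {
  cat(sprintf("<flux_record> %g +/- %g %s", x$value, x$sigma, x$units))
  if (!is.na(x$n_counted)) cat(sprintf(" (n counted = %d)", x$n_counted))
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
format.flux_record <- function(x, ...) {
  sprintf("%g +/- %g %s", x$value, x$sigma, x$units)
}

# Internal guard: two records must share units before they are combined.
check_same_units <- function(a, b) {
  if (!identical(a$units, b$units)) {
    stop("flux units differ: '", a$units, "' vs '", b$units,
         "'; refusing to combine cell-number and carbon fluxes")
  }
  invisible(TRUE)
}

#' Is an object a flux record?
#' @param x Object to test.
#' @return Logical scalar.
#' @export
is_flux_record <- function(x) inherits(x, "flux_record")
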