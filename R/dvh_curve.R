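#' Construct a cumulative DVH curve
#'
#' A `dvh_curve` is a cumulative dose-volume histogram: for every dose level
#' on a shared grid it stores the fraction of the organ volume receiving at
#' least that dose. All curves in a cohort share one dose grid, which makes
#' them directly comparable bin by bin and lets a cohort be compressed by a
#' common principal-component basis.
#'
#' @param dose_grid Numeric vector of dose values in Gy; strictly increasing
#'   and starting at 0.
#' @param volume_fraction Numeric vector, same length as `dose_grid`;
#'   fractional volume in `[0, 1]`, non-increasing along the grid, equal to 1
#'   at 0 Gy.
#' @param prescription_dose Prescription dose in Gy; anchors the linear
#'   relative weighting scheme.
#' @param validate If `FALSE`, skip invariant checks (internal fast path).
#'
#' @return An object of class `dvh_curve` with fields `dose_grid`,
#'   `volume_fraction` and `prescription_dose`.
#' @seealso [make_dose_grid()], [decode_dvh()]
#' @export
dvh_curve <- function(dose_grid, volume_fraction, prescription_dose,
                      validate = TRUE) {
  dose_grid <- as.numeric(dose_grid)
  volume_fraction <- as.numeric(volume_fraction)
  if (validate) {
    if (length(dose_grid) != length(volume_fraction)) {
      stop("dose_grid and volume_fraction must have equal length")
    }
    if (dose_grid[1] != 0) stop("dose_grid must start at 0 Gy")
    if (any(diff(dose_grid) <= 0)) stop("dose_grid must be strictly increasing")
    if (any(volume_fraction < -1e-12) || any(volume_fraction > 1 + 1e-12)) {
      stop("volume_fraction values must lie in [0, 1]")
    }
    if (any(diff(volume_fraction) > 1e-12)) {
      stop("volume_fraction must be non-increasing along the dose grid")
    }
    if (abs(volume_fraction[1] - 1) > 1e-12) {
      stop("volume_fraction at 0 Gy must equal 1")
    }
    if (!is.numeric(prescription_dose) || length(prescription_dose) != 1 ||
        prescription_dose <= 0) {
      stop("prescription_dose must be a positive scalar (Gy)")
    }
  }
  structure(
    list(dose_grid = dose_grid, volume_fraction = volume_fraction,
         prescription_dose = as.numeric(prescription_dose)),
    class = "dvh_curve"
  )
}

#' Default cohort dose grid
#'
#' Uniform grid from 0 to `factor` times the prescription dose. The default
#' (111 bins up to 1.1 x prescription) covers the full clinically relevant
#' range with sub-Gy resolution for typical prescriptions.
#'
#' @param prescription_dose Prescription dose in Gy.
#' @param n_bins Number of grid points.
#' @param factor Upper end of the grid as a multiple of the prescription.
#' @return Numeric dose grid in Gy.
#' @export
make_dose_grid <- function(prescription_dose, n_bins = 111, factor = 1.1) {
  seq(0, factor * prescription_dose, length.out = n_bins)
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf(
    "<dvh_curve> %d bins, 0-%.1f Gy, prescription %.1f Gy\n",
    length(x$dose_grid), max(x$dose_grid), x$prescription_dose
  ))
  invisible(x)
}

# Shared-grid check used by encode/wrmse; exact equality is required because
# cohort curves are meant to be sampled on the identical grid object.
check_same_grid <- function(a, b) {
  if (length(a) != length(b) || any(abs(a - b) > 1e-9)) {
    stop("dose grids do not match")
  }
  invisible(TRUE)
}

#' Project a raw curve onto the space of valid DVH curves
#'
#' Clips to `[0, 1]`, enforces monotone non-increase by a running minimum from
#' low to high dose, and forces the value at 0 Gy to 1. This is the minimal
#' post-processing applied after decoding principal-component scores, which
#' can otherwise produce slightly invalid curves.
#'
#' @param v Numeric vector of raw fractional volumes.
#' @return Valid fractional-volume vector.
#' @export
postprocess_volume <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  v[1] <- 1
  cummin(v)
}
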