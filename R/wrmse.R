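#' Weighting schemes for DVH comparison
#'
#' Dose-dependent weights emphasize the clinically important region of a DVH
#' when scoring a prediction against the clinical curve:
#'
#' * `linear_relative` — weights rise linearly from `w_low` (default 50) at
#'   0 Gy to `w_high` (default 100) at the prescription dose and stay at
#'   `w_high` beyond it. Used for serial-dose organs such as bladder and
#'   rectum, where the high-dose tail matters most.
#' * `gaussian_median` — a Gaussian of standard deviation `sd_gy` (default
#'   2 Gy) centered at the clinical curve's median dose (the dose at which
#'   the cumulative volume crosses 0.5). Used for parotid-type organs where
#'   the median dose drives toxicity. Weights are floored at `1e-12` so all
#'   bins remain strictly positive.
#' * `constant` — all-ones weights; the weighted error then reduces exactly
#'   to the ordinary RMSE.
#'
#' @param kind One of `"linear_relative"`, `"gaussian_median"`, `"constant"`.
#' @param w_low,w_high Endpoints of the linear ramp.
#' @param sd_gy Standard deviation of the Gaussian weighting, in Gy.
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(kind = c("linear_relative", "gaussian_median", "constant"),
                          w_low = 50, w_high = 100, sd_gy = 2) {
  kind <- match.arg(kind)
  structure(list(kind = kind, w_low = w_low, w_high = w_high, sd_gy = sd_gy),
            class = "weight_scheme")
}

#' Median dose of a DVH curve
#'
#' Dose at which the cumulative fractional volume first crosses 0.5, located
#' by linear interpolation between the bracketing grid points.
#'
#' @param curve A [dvh_curve()].
#' @return Median dose in Gy.
#' @export
median_dose <- function(curve) {
  v <- curve$volume_fraction
  d <- curve$dose_grid
  idx <- which(v <= 0.5)
  if (length(idx) == 0) {
    stop("median dose undefined: curve never crosses volume fraction 0.5")
  }
  i <- idx[1]
  if (i == 1 || v[i] == 0.5) return(d[i])
  # linear interpolation across the first downward crossing
  d[i - 1] + (v[i - 1] - 0.5) / (v[i - 1] - v[i]) * (d[i] - d[i - 1])
}

#' Raw per-bin weights for a scheme and reference curve
#'
#' @param scheme A [weight_scheme()].
#' @param truth The clinical reference [dvh_curve()]; supplies the
#'   prescription dose (linear scheme) or the median dose (Gaussian scheme).
#' @return Numeric vector of strictly positive raw weights, one per dose bin.
#' @export
make_weight_vector <- function(scheme, truth) {
  d <- truth$dose_grid
  switch(scheme$kind,
    constant = rep(1, length(d)),
    linear_relative = {
      rx <- truth$prescription_dose
      scheme$w_low + (scheme$w_high - scheme$w_low) * pmin(d / rx, 1)
    },
    gaussian_median = {
      d50 <- median_dose(truth)
      pmax(exp(-(d - d50)^2 / (2 * scheme$sd_gy^2)), 1e-12)
    }
  )
}

#' Weighted root mean squared error between two DVH curves
#'
#' `sqrt(sum_i w''_i (truth_i - pred_i)^2)` where `w''_i = w_i / sum_j w_j`
#' are the normalized weights from [make_weight_vector()]. With the constant
#' scheme this is exactly the standard RMSE over dose bins.
#'
#' @param truth Clinical reference [dvh_curve()] (also defines the weights).
#' @param prediction Predicted [dvh_curve()] on the same grid.
#' @param scheme A [weight_scheme()]; default constant.
#' @return Non-negative scalar error on the fractional-volume scale.
#' @export
wrmse <- function(truth, prediction, scheme = weight_scheme("constant")) {
  check_same_grid(truth$dose_grid, prediction$dose_grid)
  w <- make_weight_vector(scheme, truth)
  resid <- truth$volume_fraction - prediction$volume_fraction
  sqrt(sum(w / sum(w) * resid^2))
}
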