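#' Fit a principal-component basis for a cohort of DVH curves
#'
#' Performs PCA on the matrix of cumulative DVH curves (cases x dose bins)
#' and retains the leading `n_pc` components. A DVH is then represented by
#' `n_pc` principal-component scores (PCS), which become the regression
#' targets of the dose-prediction models.
#'
#' Component signs are fixed so that each component's largest-magnitude entry
#' is positive, making the basis reproducible across platforms.
#'
#' @param curves List of [dvh_curve()] objects on a common dose grid.
#' @param n_pc Number of components to retain (default 3).
#' @return An object of class `dvh_basis` with fields `dose_grid`,
#'   `mean_curve`, `components` (`n_pc` x bins matrix, rows orthonormal),
#'   `explained_variance` (per retained component), `total_variance`,
#'   `n_pc` and `prescription_dose`.
#' @export
fit_dvh_basis <- function(curves, n_pc = 3) {
  if (length(curves) < n_pc + 1) {
    stop(sprintf("need at least n_pc + 1 = %d curves, got %d",
                 n_pc + 1, length(curves)))
  }
  grid <- curves[[1]]$dose_grid
  for (cv in curves[-1]) check_same_grid(grid, cv$dose_grid)
  if (n_pc < 1 || n_pc > length(grid)) {
    stop("n_pc must be between 1 and the number of grid points")
  }
  n_pc <- as.integer(n_pc)
  V <- do.call(rbind, lapply(curves, `[[`, "volume_fraction"))
  mean_curve <- colMeans(V)
  Vc <- sweep(V, 2, mean_curve)
  # SVD of the centered matrix; eigenvalues of the sample covariance are
  # d^2 / (N - 1).
  sv <- svd(Vc, nu = 0, nv = min(dim(Vc)))
  n <- nrow(V)
  ev_all <- sv$d^2 / (n - 1)
  comps <- t(sv$v[, seq_len(n_pc), drop = FALSE])
  for (j in seq_len(n_pc)) {
    i_max <- which.max(abs(comps[j, ]))
    if (comps[j, i_max] < 0) comps[j, ] <- -comps[j, ]
  }
  structure(
    list(dose_grid = grid,
         mean_curve = mean_curve,
         components = comps,
         explained_variance = ev_all[seq_len(n_pc)],
         total_variance = sum(ev_all),
         n_pc = n_pc,
         prescription_dose = curves[[1]]$prescription_dose),
    class = "dvh_basis"
  )
}

#' @export
print.dvh_basis <- function(x, ...) {
  pct <- if (x$total_variance > 0) {
    100 * sum(x$explained_variance) / x$total_variance
  } else 100
  cat(sprintf("<dvh_basis> %d components over %d bins (%.1f%% variance)\n",
              x$n_pc, length(x$dose_grid), pct))
  invisible(x)
}

#' Encode a DVH curve as principal-component scores
#'
#' Projects the centered curve onto each basis component. Because the
#' components are orthonormal these are ordinary inner products.
#'
#' @param curve A [dvh_curve()] on the basis grid.
#' @param basis A [fit_dvh_basis()] result.
#' @return Numeric vector of `n_pc` scores.
#' @export
encode_dvh <- function(curve, basis) {
  check_same_grid(curve$dose_grid, basis$dose_grid)
  as.numeric(basis$components %*% (curve$volume_fraction - basis$mean_curve))
}

#' Decode principal-component scores back into a valid DVH curve
#'
#' Reconstructs `mean + sum(score_j * component_j)` and applies the minimal
#' projection onto valid DVHs: values clipped to `[0, 1]`, monotone
#' non-increase enforced by a running minimum, and the 0-Gy bin forced to 1
#' (see [postprocess_volume()]).
#'
#' @param scores Numeric vector of length `basis$n_pc`.
#' @param basis A [fit_dvh_basis()] result.
#' @param prescription_dose Prescription dose in Gy; defaults to the dose
#'   recorded in the basis.
#' @return A [dvh_curve()].
#' @export
decode_dvh <- function(scores, basis, prescription_dose = basis$prescription_dose) {
  if (length(scores) != basis$n_pc) {
    stop(sprintf("scores has length %d but basis retains %d components",
                 length(scores), basis$n_pc))
  }
  raw <- basis$mean_curve + as.numeric(crossprod(basis$components, scores))
  dvh_curve(basis$dose_grid, postprocess_volume(raw), prescription_dose,
            validate = FALSE)
}
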