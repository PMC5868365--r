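#' Ground-truth DVH family for simulation
#'
#' Builds the generative curve model used by the synthetic cohort: a monotone
#' sigmoid falloff as the mean curve plus three smooth, mutually orthonormal
#' modes obtained by Gram-Schmidt orthonormalization of the sigmoid's
#' parametric derivatives (horizontal shift, slope change, curvature). Small
#' linear combinations of the modes move the curve the way real plan
#' variation does: mode 1 shifts dose up or down (positive score = more dose,
#' i.e. inferior sparing), mode 2 steepens or flattens the falloff.
#'
#' Modes are tapered to zero at 0 Gy so every in-budget curve keeps volume
#' fraction 1 at zero dose, and `score_budget` records per-mode score
#' magnitudes within which raw curves remain valid without post-processing.
#'
#' @param grid Dose grid in Gy (see [make_dose_grid()]).
#' @param prescription_dose Prescription dose in Gy.
#' @param seed Seed; jitters the sigmoid center/width a few percent so
#'   different families are not bin-identical.
#' @return An object of class `dvh_family`: `dose_grid`, `mean_curve`,
#'   `modes` (3 x bins, orthonormal rows), `score_budget`,
#'   `prescription_dose`.
#' @export
make_dvh_family <- function(grid, prescription_dose = 78, seed = 1) {
  jit <- with_seed(seed, stats::runif(2, -0.02, 0.02))
  d0 <- (0.5 + jit[1]) * prescription_dose
  s <- (0.12 + jit[2] / 4) * prescription_dose
  sig <- function(z) 1 / (1 + exp(-z))
  v0 <- sig((d0 - grid) / s)
  mean_curve <- v0 / v0[1]
  u <- (d0 - grid) / s
  e <- sig(u) * (1 - sig(u))        # logistic density: sigmoid derivative
  # super-Gaussian window confines the modes to the falloff region, where the
  # mean curve has slack against the [0, 1] and monotonicity constraints
  window <- exp(-((grid - d0) / (2.2 * s))^4)
  raw <- rbind(
    e,                              # shift mode
    e * u,                          # width/slope mode
    e * (1 - 2 * sig(u))            # curvature mode
  )
  raw <- sweep(raw, 2, window, `*`)
  raw[, 1] <- 0                     # volume fraction at 0 Gy stays exactly 1
  # Gram-Schmidt
  modes <- raw
  for (j in seq_len(nrow(raw))) {
    v <- raw[j, ]
    if (j > 1) {
      for (i in seq_len(j - 1)) v <- v - sum(v * modes[i, ]) * modes[i, ]
    }
    modes[j, ] <- v / sqrt(sum(v^2))
  }
  # orient mode 1 so a positive score raises volume (inferior sparing)
  if (sum(modes[1, ]) < 0) modes[1, ] <- -modes[1, ]
  structure(
    list(dose_grid = grid, mean_curve = mean_curve, modes = modes,
         score_budget = c(0.45, 0.25, 0.15),
         prescription_dose = prescription_dose),
    class = "dvh_family"
  )
}

# Decode true scores through the family (same minimal projection as the
# model-side decoder).
family_decode <- function(family, scores) {
  raw <- family$mean_curve + as.numeric(crossprod(family$modes, scores))
  dvh_curve(family$dose_grid, postprocess_volume(raw),
            family$prescription_dose, validate = FALSE)
}

#' Synthetic cohort configuration
#'
#' Defines the statistical structure the prediction method assumes: features
#' drawn from a compound-symmetric multivariate normal, a linear map `B` from
#' features to the three DVH mode scores, and additive Gaussian score noise.
#' The default `B` is sparse by row (a handful of features drive each mode)
#' and is rescaled so the mode-score signal standard deviations equal
#' `signal_sd`. The default noise level is set from the signal so a clean
#' least-squares fit explains about 70% of the score variance
#' (`noise_sd = signal_sd * sqrt(3/7)`).
#'
#' @param n_cases Number of cases.
#' @param n_features Number of anatomical features (default 9).
#' @param feature_correlation Pairwise feature correlation (compound
#'   symmetry; default 0.5).
#' @param signal_sd Target standard deviation of `B x` per mode.
#' @param noise_sd Score noise SD per mode; default gives R^2 of 0.7.
#' @param prescription_dose Gy.
#' @param n_bins Dose-grid bins.
#' @param true_coefficients Optional 3 x `n_features` matrix `B`; default as
#'   described.
#' @param family_seed Seed for [make_dvh_family()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 50, n_features = 9,
                          feature_correlation = 0.5,
                          signal_sd = c(0.15, 0.08, 0.04),
                          noise_sd = signal_sd * sqrt(3 / 7),
                          prescription_dose = 78, n_bins = 111,
                          true_coefficients = NULL, family_seed = 1) {
  if (feature_correlation <= -1 / (n_features - 1) || feature_correlation >= 1) {
    stop("feature_correlation leaves the covariance non-positive-definite")
  }
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  Sigma <- matrix(feature_correlation, n_features, n_features)
  diag(Sigma) <- 1
  if (is.null(true_coefficients)) {
    # Sparse rows: a handful of anatomical features drives each DVH mode.
    # This mirrors the clinical regime the method targets — shrinkage-heavy
    # learners underfit the sparse mapping while greedy selection
    # destabilizes at small N — so the base learners genuinely differ.
    D <- matrix(0, 3, n_features)
    idx1 <- intersect(c(1, 4), seq_len(n_features))
    idx2 <- intersect(c(2, 5, 8), seq_len(n_features))
    idx3 <- intersect(c(3, 7), seq_len(n_features))
    D[1, idx1] <- c(1, 0.6)[seq_along(idx1)]
    D[2, idx2] <- c(1, 0.7, 0.4)[seq_along(idx2)]
    D[3, idx3] <- c(1, 0.5)[seq_along(idx3)]
    true_coefficients <- D
  }
  B <- true_coefficients
  for (j in 1:3) {
    s <- sqrt(drop(B[j, ] %*% Sigma %*% B[j, ]))
    if (s > 0) B[j, ] <- B[j, ] * signal_sd[j] / s
  }
  structure(
    list(n_cases = n_cases, n_features = n_features,
         feature_correlation = feature_correlation, Sigma = Sigma,
         signal_sd = signal_sd, noise_sd = noise_sd,
         prescription_dose = prescription_dose, n_bins = n_bins,
         true_coefficients = B, family_seed = family_seed),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort
#'
#' Draws features from the configured multivariate normal, computes true mode
#' scores `B x + noise`, and decodes each score vector through the DVH family
#' into a clinical-style cumulative DVH.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return An object of class `dvh_cohort`: `features` (N x P matrix),
#'   `case_ids`, `dvhs` (list of [dvh_curve()]), `true_pcs` (N x 3 true
#'   scores), `noise` (the additive score noise, kept so contamination can
#'   rewrite the signal without redrawing noise), `labels` (all "normal"),
#'   `family`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  n <- config$n_cases
  p <- config$n_features
  family <- make_dvh_family(make_dose_grid(config$prescription_dose,
                                           config$n_bins),
                            config$prescription_dose, seed = config$family_seed)
  draws <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p)
    E <- matrix(stats::rnorm(n * 3), n, 3)
    list(Z = Z, E = E)
  })
  X <- draws$Z %*% chol(config$Sigma)
  colnames(X) <- paste0("f", seq_len(p))
  noise <- sweep(draws$E, 2, config$noise_sd, `*`)
  pcs <- X %*% t(config$true_coefficients) + noise
  dvhs <- lapply(seq_len(n), function(i) family_decode(family, pcs[i, ]))
  structure(
    list(features = X, case_ids = sprintf("case_%03d", seq_len(n)),
         dvhs = dvhs, true_pcs = pcs, noise = noise,
         labels = rep("normal", n), family = family, config = config),
    class = "dvh_cohort"
  )
}

#' @export
print.dvh_cohort <- function(x, ...) {
  cat(sprintf("<dvh_cohort> %d cases, %d features, %d dose bins (%s)\n",
              nrow(x$features), ncol(x$features),
              length(x$family$dose_grid),
              paste(unique(x$labels), collapse = "/")))
  invisible(x)
}

#' Outlier contamination specification
#'
#' Three mechanisms mirror the ways clinical training sets go wrong:
#'
#' * `anatomical` — feature vectors pushed `feature_shift_sd` standard
#'   deviations along a direction in feature space, with the mode-1 response
#'   acquiring a quadratic departure that only activates beyond the normal
#'   feature range (the linear model is locally right, globally wrong).
#' * `dosimetric_inferior` — plans with systematically worse sparing: a fixed
#'   positive offset added to the mode-1 score.
#' * `mislabeled` — cases following a different response mapping `B_alt`
#'   (default: the true `B` with feature columns reversed).
#'
#' @param kind Mechanism.
#' @param n_outliers How many cases to contaminate (the last `n_outliers`
#'   cases of the cohort, recorded in the returned labels).
#' @param feature_shift_sd Anatomical shift magnitude in SD units (default 4).
#' @param quad_coef Quadratic departure coefficient (anatomical); default
#'   half the mode-1 signal SD per squared SD beyond the 2-SD edge.
#' @param offset Mode-1 score offset (dosimetric); default 5 x the mode-1
#'   noise SD.
#' @param B_alt Alternative 3 x P coefficient matrix (mislabeled).
#' @param direction Unit direction in feature space for the anatomical shift;
#'   default equal loading on all features.
#' @return An object of class `outlier_spec`.
#' @export
outlier_spec <- function(kind = c("anatomical", "dosimetric_inferior", "mislabeled"),
                         n_outliers, feature_shift_sd = 4, quad_coef = NULL,
                         offset = NULL, B_alt = NULL, direction = NULL) {
  kind <- match.arg(kind)
  if (n_outliers < 0) stop("n_outliers must be non-negative")
  structure(list(kind = kind, n_outliers = n_outliers,
                 feature_shift_sd = feature_shift_sd, quad_coef = quad_coef,
                 offset = offset, B_alt = B_alt, direction = direction),
            class = "outlier_spec")
}

#' Inject outliers into a synthetic cohort
#'
#' Contaminates the last `n_outliers` cases according to the mechanism in
#' `spec` and regenerates their DVHs; the additive score noise drawn at
#' cohort generation is reused, so a zero-magnitude spec returns the cohort
#' unchanged. Labels record the mechanism for filter-recall evaluation.
#'
#' @param cohort A [generate_cohort()] result.
#' @param spec An [outlier_spec()].
#' @return The contaminated `dvh_cohort` (labels updated).
#' @export
inject_outliers <- function(cohort, spec) {
  n <- nrow(cohort$features)
  if (spec$n_outliers >= n) stop("n_outliers must be smaller than the cohort")
  if (spec$n_outliers == 0) return(cohort)
  cfg <- cohort$config
  idx <- seq.int(n - spec$n_outliers + 1, n)
  B <- cfg$true_coefficients
  if (spec$kind == "anatomical") {
    u <- spec$direction
    if (is.null(u)) u <- rep(1, cfg$n_features)
    u <- u / sqrt(sum(u^2))
    t_sd <- sqrt(drop(u %*% cfg$Sigma %*% u))
    quad <- spec$quad_coef
    if (is.null(quad)) quad <- 0.5 * cfg$signal_sd[1]
    cohort$features[idx, ] <- cohort$features[idx, , drop = FALSE] +
      spec$feature_shift_sd * t_sd * matrix(u, length(idx), cfg$n_features,
                                            byrow = TRUE)
    pcs <- cohort$features[idx, , drop = FALSE] %*% t(B) +
      cohort$noise[idx, , drop = FALSE]
    t_proj <- as.numeric(cohort$features[idx, , drop = FALSE] %*% u) / t_sd
    pcs[, 1] <- pcs[, 1] + quad * pmax(t_proj - 2, 0)^2
    cohort$true_pcs[idx, ] <- pcs
  } else if (spec$kind == "dosimetric_inferior") {
    off <- spec$offset
    if (is.null(off)) off <- 5 * cfg$noise_sd[1]
    cohort$true_pcs[idx, 1] <- cohort$true_pcs[idx, 1] + off
  } else {  # mislabeled
    B_alt <- spec$B_alt
    if (is.null(B_alt)) B_alt <- B[, rev(seq_len(ncol(B))), drop = FALSE]
    cohort$true_pcs[idx, ] <- cohort$features[idx, , drop = FALSE] %*% t(B_alt) +
      cohort$noise[idx, , drop = FALSE]
  }
  for (i in idx) {
    cohort$dvhs[[i]] <- family_decode(cohort$family, cohort$true_pcs[i, ])
  }
  cohort$labels[idx] <- spec$kind
  cohort
}

#' Scenario presets for the robustness experiments
#'
#' Four canonical experiment designs; training and validation cases are drawn
#' from the same generator and the validation set is always outlier-free:
#'
#' * `small_training` — 20 training / 146 validation cases, no outliers.
#' * `anatomical` — 40 normal + 10 anatomical-outlier training cases /
#'   111 validation.
#' * `dosimetric_inferior` — 40 normal + 10 inferior-sparing training cases /
#'   110 validation.
#' * `mislabeled` — 80 normal + 10 alternative-mapping training cases /
#'   148 validation.
#'
#' @param name Scenario name.
#' @param seed Integer seed.
#' @param config Base [cohort_config()] (its `n_cases` is overridden).
#' @return List with `train` and `validation` cohorts (labels on `train`
#'   identify injected outliers).
#' @export
scenario_preset <- function(name = c("small_training", "anatomical",
                                     "dosimetric_inferior", "mislabeled"),
                            seed = 1, config = cohort_config()) {
  name <- match.arg(name)
  sizes <- switch(name,
    small_training      = list(train = 20, out = 0, val = 146),
    anatomical          = list(train = 50, out = 10, val = 111),
    dosimetric_inferior = list(train = 50, out = 10, val = 110),
    mislabeled          = list(train = 90, out = 10, val = 148)
  )
  config$n_cases <- sizes$train + sizes$val
  big <- generate_cohort(config, seed = seed)
  train <- subset_cohort(big, seq_len(sizes$train))
  validation <- subset_cohort(big, sizes$train + seq_len(sizes$val))
  if (sizes$out > 0) {
    kind <- if (name == "anatomical") "anatomical"
            else if (name == "dosimetric_inferior") "dosimetric_inferior"
            else "mislabeled"
    train <- inject_outliers(train, outlier_spec(kind, sizes$out))
  }
  list(train = train, validation = validation, scenario = name, seed = seed)
}

#' Extract a subset of cohort cases
#'
#' @param cohort A `dvh_cohort`.
#' @param idx Integer case indices to keep.
#' @return A `dvh_cohort` with the selected cases.
#' @export
subset_cohort <- function(cohort, idx) {
  cohort$features <- cohort$features[idx, , drop = FALSE]
  cohort$case_ids <- cohort$case_ids[idx]
  cohort$dvhs <- cohort$dvhs[idx]
  cohort$true_pcs <- cohort$true_pcs[idx, , drop = FALSE]
  cohort$noise <- cohort$noise[idx, , drop = FALSE]
  cohort$labels <- cohort$labels[idx]
  cohort$config$n_cases <- length(idx)
  cohort
}
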