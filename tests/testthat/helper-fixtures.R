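# Shared fixture builders; everything is generated in code under fixed seeds.

# A small set of valid curves spanning a known low-rank space: mean sigmoid
# plus `rank` orthonormal modes with controlled score spread.
fixture_curves <- function(n, rank = 3, seed = 1, noise = 0,
                           prescription = 78) {
  fam <- make_dvh_family(make_dose_grid(prescription), prescription,
                         seed = seed)
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- numeric(3)
      s[seq_len(rank)] <- stats::runif(rank, -0.5, 0.5) *
        fam$score_budget[seq_len(rank)]
      curve <- dvhstack:::family_decode(fam, s)
      if (noise > 0) {
        v <- postprocess_volume(curve$volume_fraction +
                                  stats::rnorm(length(curve$dose_grid), 0,
                                               noise))
        curve <- dvh_curve(curve$dose_grid, v, prescription)
      }
      curve
    })
  })
}

# Random regression problem with standardized features.
fixture_problem <- function(n = 20, p = 5, seed = 1, beta = NULL,
                            noise = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    if (is.null(beta)) beta <- stats::rnorm(p)
    y <- drop(X %*% beta) + stats::rnorm(n, 0, noise)
  })
  std <- standardize_features(X)
  list(X = std$values, X_raw = X, y = y, beta = beta, std = std)
}

# Brute-force forward selection used as the stepwise oracle: per step, fit
# every candidate model with lm() and pick the smallest entry p-value.
oracle_stepwise_sequence <- function(X, y, p_enter) {
  p <- ncol(X)
  selected <- integer(0)
  remaining <- seq_len(p)
  repeat {
    if (length(remaining) == 0) break
    pvals <- vapply(remaining, function(j) {
      df <- data.frame(y = y, X[, c(selected, j), drop = FALSE])
      fit <- stats::lm(y ~ ., data = df)
      cf <- summary(fit)$coefficients
      if (nrow(cf) < length(selected) + 2) return(NA_real_)
      cf[nrow(cf), 4]
    }, numeric(1))
    if (all(is.na(pvals))) break
    best <- which.min(pvals)
    if (pvals[best] >= p_enter) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  selected
}

# Objective of the penalized regression problem (intercept unpenalized).
penalized_objective <- function(X, y, intercept, beta, l1, l2) {
  sum((y - intercept - X %*% beta)^2) + l1 * sum(abs(beta)) +
    l2 * sum(beta^2)
}
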