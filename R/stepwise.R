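# OLS on an explicit design via the normal equations (p is small here).
# Returns NULL when the design is rank deficient.
ols_with_tests <- function(M, y) {
  XtX <- crossprod(M)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  XtXinv <- chol2inv(ch)
  cf <- as.numeric(XtXinv %*% crossprod(M, y))
  res <- y - as.numeric(M %*% cf)
  df <- nrow(M) - ncol(M)
  if (df < 1) return(NULL)
  s2 <- sum(res^2) / df
  se <- sqrt(pmax(s2 * diag(XtXinv), 0))
  tval <- ifelse(se > 0, cf / se, Inf)
  list(coefficients = cf, p_values = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Forward stepwise regression with p-value entry
#'
#' At each step the candidate feature whose coefficient t-test (equivalently
#' partial F-test) in the extended model has the smallest p-value is added,
#' provided that p-value is below `p_enter`; selection stops otherwise, or
#' when adding any candidate would make the design rank deficient. The
#' selected set is then refitted by ordinary least squares; unselected
#' coefficients are exactly zero. Ties in the entry p-value go to the lower
#' feature index.
#'
#' @param X Standardized feature matrix.
#' @param y Response vector.
#' @param p_enter Entry threshold in `(0, 1)`; default 0.05.
#' @return A `base_learner_model` (see [fit_penalized()]).
#' @export
fit_stepwise <- function(X, y, p_enter = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  selected <- integer(0)
  remaining <- seq_len(p)
  repeat {
    if (length(remaining) == 0) break
    if (n - (length(selected) + 2) < 1) break  # no residual df for a t-test
    best_p <- Inf
    best_j <- NA_integer_
    for (j in remaining) {
      M <- cbind(1, X[, c(selected, j), drop = FALSE])
      fit <- ols_with_tests(M, y)
      if (is.null(fit)) next  # rank deficient with j added
      pv <- fit$p_values[length(fit$p_values)]
      if (is.finite(pv) && pv < best_p) {
        best_p <- pv
        best_j <- j
      }
    }
    if (!is.finite(best_p) || best_p >= p_enter) break
    selected <- c(selected, best_j)
    remaining <- setdiff(remaining, best_j)
  }
  beta <- numeric(p)
  if (length(selected) == 0) {
    intercept <- mean(y)
  } else {
    M <- cbind(1, X[, selected, drop = FALSE])
    fit <- ols_with_tests(M, y)
    if (is.null(fit)) {  # cannot happen if entry checks passed; be safe
      cf <- stats::lm.fit(M, y)$coefficients
      cf[is.na(cf)] <- 0
      fit <- list(coefficients = cf)
    }
    intercept <- fit$coefficients[1]
    beta[selected] <- fit$coefficients[-1]
  }
  model <- new_base_learner(
    learner_spec("stepwise", p_enter = p_enter),
    intercept = intercept, coefficients = beta,
    selected = sort(selected), feature_names = colnames(X)
  )
  model$selection_order <- selected  # entry order, before sorting
  model
}

#' Fit any base learner from its spec
#'
#' Dispatches to [fit_stepwise()] or [fit_penalized()]; penalized specs with
#' unset penalties first run [select_penalty()] with the given seed.
#'
#' @param X Standardized feature matrix.
#' @param y Response vector.
#' @param spec A [learner_spec()].
#' @param seed Seed for penalty-selection fold assignment.
#' @param grid Optional penalty-magnitude grid passed to [select_penalty()].
#' @param n_folds CV folds for penalty selection.
#' @return A `base_learner_model`.
#' @export
fit_learner <- function(X, y, spec, seed = 1, grid = NULL, n_folds = 5) {
  if (spec$kind == "stepwise") {
    return(fit_stepwise(X, y, p_enter = spec$p_enter))
  }
  needs_l1 <- spec$kind %in% c("lasso", "elastic_net") && is.null(spec$lambda1)
  needs_l2 <- spec$kind %in% c("ridge", "elastic_net") && is.null(spec$lambda2)
  if (needs_l1 || needs_l2) {
    spec <- select_penalty(X, y, spec, grid = grid,
                           n_folds = min(n_folds, nrow(X)), seed = seed)
  }
  fit_penalized(X, y, spec)
}
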