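#' Fit a penalized linear base learner
#'
#' Minimizes the residual-sum-of-squares objective
#' `||y - X b||^2 + lambda1 ||b||_1 + lambda2 ||b||_2^2` by cyclic coordinate
#' descent with an unpenalized intercept. The objective is kept on the raw
#' RSS scale (no `1/N`), so penalty magnitudes are directly comparable with
#' the null-path bound `max_j |2 x_j' y|` above which the lasso solution is
#' exactly zero.
#'
#' @param X Standardized feature matrix (see [standardize_features()]).
#' @param y Response vector (one principal-component score per case).
#' @param spec A [learner_spec()] of kind ridge, lasso or elastic_net with
#'   penalties set.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param maxit Iteration cap; exceeding it is an error reporting the count.
#' @return An object of class `base_learner_model` with fields `spec`,
#'   `intercept`, `coefficients`, `selected_features` and `feature_names`.
#' @export
fit_penalized <- function(X, y, spec, tol = 1e-8, maxit = 1000000L) {
  if (!spec$kind %in% c("ridge", "lasso", "elastic_net")) {
    stop("fit_penalized requires a ridge/lasso/elastic_net spec")
  }
  X <- as.matrix(X)
  l1 <- if (is.null(spec$lambda1)) 0 else spec$lambda1
  l2 <- if (is.null(spec$lambda2)) 0 else spec$lambda2
  if (spec$kind == "ridge" && is.null(spec$lambda2)) {
    stop("ridge spec has no lambda2 set; run select_penalty() first")
  }
  if (spec$kind == "lasso" && is.null(spec$lambda1)) {
    stop("lasso spec has no lambda1 set; run select_penalty() first")
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  ybar <- mean(y)
  fit <- .enet_cd(Xc, y - ybar, l1, l2, numeric(ncol(X)), tol, as.integer(maxit))
  if (!fit$converged) {
    stop(sprintf("coordinate descent did not converge within %d iterations",
                 fit$iters))
  }
  beta <- as.numeric(fit$beta)
  new_base_learner(spec, intercept = ybar - sum(center * beta),
                   coefficients = beta,
                   selected = which(beta != 0),
                   feature_names = colnames(X))
}

new_base_learner <- function(spec, intercept, coefficients, selected,
                             feature_names) {
  structure(list(spec = spec, intercept = intercept,
                 coefficients = coefficients,
                 selected_features = selected,
                 feature_names = feature_names),
            class = "base_learner_model")
}

#' @export
print.base_learner_model <- function(x, ...) {
  cat(sprintf("<base_learner_model> %s: %d/%d nonzero coefficients\n",
              x$spec$label, sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' Predict from a fitted base learner
#'
#' @param object A `base_learner_model`.
#' @param newdata Matrix (or single row) of features standardized with the
#'   training parameters.
#' @param ... Unused.
#' @return Numeric vector of predictions `intercept + X b`.
#' @export
predict.base_learner_model <- function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
             else as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop(sprintf("model has %d features but newdata has %d",
                 length(object$coefficients), ncol(newdata)))
  }
  as.numeric(object$intercept + newdata %*% object$coefficients)
}

# Penalty-magnitude grid: n_grid log-spaced points from 1e-4 up to the
# null-path bound max_j |2 x_j' y_c| (computed on the centered problem),
# ordered large-to-small for warm-started path fits.
penalty_grid <- function(X, y, n_grid = 20) {
  Xc <- sweep(X, 2, colMeans(X))
  lmax <- max(abs(2 * crossprod(Xc, y - mean(y))))
  lmax <- max(lmax, 1e-3)  # degenerate all-zero signal still needs a grid
  exp(seq(log(lmax), log(1e-4), length.out = n_grid))
}

# Map a scalar penalty magnitude to (lambda1, lambda2) for a family member.
penalty_pair <- function(spec, magnitude) {
  switch(spec$kind,
    ridge = c(0, magnitude),
    lasso = c(magnitude, 0),
    elastic_net = c(magnitude, spec$ratio * magnitude),
    stop("no penalty for kind ", spec$kind))
}

#' Select the penalty magnitude by internal cross-validation
#'
#' Evaluates a log-spaced grid of penalty magnitudes (default 20 points from
#' `1e-4` to the null-path bound) by k-fold cross-validation and returns the
#' spec with the magnitude minimizing mean squared out-of-fold error.
#' Elastic-net members hold their `lambda2/lambda1` ratio fixed while the
#' magnitude is tuned. Ties are broken toward the larger penalty. Fold
#' assignment is seeded, so selection is deterministic.
#'
#' @param X Standardized feature matrix.
#' @param y Response vector.
#' @param spec Template [learner_spec()] (penalties unset).
#' @param grid Optional vector of penalty magnitudes; defaults to
#'   [penalty_grid()] on `(X, y)`.
#' @param n_folds Number of CV folds (default 5, capped at `N`).
#' @param seed Integer seed for the fold assignment.
#' @return The spec with `lambda1` / `lambda2` filled in.
#' @export
select_penalty <- function(X, y, spec, grid = NULL, n_folds = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_folds) stop(sprintf("N = %d is smaller than n_folds = %d", n, n_folds))
  if (is.null(grid)) grid <- penalty_grid(X, y)
  if (length(grid) == 0) stop("penalty grid is empty")
  grid <- sort(grid, decreasing = TRUE)  # first index = largest penalty
  if (length(grid) == 1) {
    lam <- penalty_pair(spec, grid)
    spec$lambda1 <- lam[1]; spec$lambda2 <- lam[2]
    return(spec)
  }
  l1s <- vapply(grid, function(m) penalty_pair(spec, m)[1], numeric(1))
  l2s <- vapply(grid, function(m) penalty_pair(spec, m)[2], numeric(1))
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  sse <- numeric(length(grid))
  for (f in seq_len(n_folds)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    center <- colMeans(Xtr)
    ybar <- mean(ytr)
    B <- .enet_path(sweep(Xtr, 2, center), ytr - ybar, l1s, l2s, 1e-8, 1000000L)
    pred <- sweep(X[test, , drop = FALSE], 2, center) %*% B + ybar
    sse <- sse + colSums((y[test] - pred)^2)
  }
  best <- which.min(sse)  # first occurrence = larger penalty on ties
  lam <- penalty_pair(spec, grid[best])
  spec$lambda1 <- lam[1]
  spec$lambda2 <- lam[2]
  spec
}
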