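#' Non-negative least squares by the Lawson-Hanson active-set method
#'
#' Solves `min_a ||y - Z a||^2 subject to a >= 0` exactly: at convergence the
#' Karush-Kuhn-Tucker conditions hold to `tol` (gradient `2 Z'(Za - y)` is
#' zero on the passive set and non-negative on the active set). Ties when
#' choosing the entering variable are broken toward the lowest index.
#'
#' @param Z N x K matrix of regressors (out-of-fold metadata predictions when
#'   used for stacking).
#' @param y Length-N response.
#' @param tol KKT tolerance (default `1e-8`, scaled by the problem norm).
#' @return Numeric vector of K non-negative coefficients.
#' @export
nnls_fit <- function(Z, y, tol = 1e-8) {
  Z <- as.matrix(Z)
  K <- ncol(Z)
  if (nrow(Z) != length(y)) stop("Z and y dimensions do not match")
  scale <- max(abs(crossprod(Z, y)), 1)
  a <- numeric(K)
  passive <- rep(FALSE, K)
  # negative gradient of the 0.5*||y - Za||^2 objective
  w <- as.numeric(crossprod(Z, y))
  it_outer <- 0L
  max_outer <- 10L * K + 50L
  while (it_outer < max_outer) {
    it_outer <- it_outer + 1L
    cand <- which(!passive & w > tol * scale)
    if (length(cand) == 0) break
    j <- cand[which.max(w[cand])]
    # which.max returns the first maximum, i.e. the lowest index on ties
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      Zp <- Z[, P, drop = FALSE]
      s <- tryCatch(
        as.numeric(chol2inv(chol(crossprod(Zp))) %*% crossprod(Zp, y)),
        error = function(e) NULL
      )
      if (is.null(s)) {  # singular passive design: drop the entering variable
        passive[j] <- FALSE
        break
      }
      if (all(s > 0)) {
        a[] <- 0
        a[P] <- s
        break
      }
      neg <- which(s <= 0)
      alpha <- min(a[P][neg] / (a[P][neg] - s[neg]))
      a[P] <- a[P] + alpha * (s - a[P])
      passive[P[a[P] <= tol]] <- FALSE
      a[!passive] <- 0
    }
    w <- as.numeric(crossprod(Z, y - Z %*% a))
  }
  a
}
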