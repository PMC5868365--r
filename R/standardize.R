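#' Standardize an anatomical feature matrix
#'
#' Z-scores each column with its training-set mean and sample standard
#' deviation (denominator `N - 1`), so that penalty terms act on comparable
#' scales across features. Constant columns are centered only (scale left at
#' 1) with a warning.
#'
#' @param X Numeric matrix, cases in rows, features in columns. No missing
#'   values allowed.
#' @return An object of class `std_features`: `values` (standardized matrix),
#'   `center`, `scale`, and `constant` (logical flag per feature).
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("feature matrix contains missing values")
  if (nrow(X) < 2) stop("need at least 2 cases to standardize")
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  constant <- scale < .Machine$double.eps^0.5
  if (any(constant)) {
    warning(sprintf("constant feature column(s) %s centered but not scaled",
                    paste(which(constant), collapse = ", ")))
    scale[constant] <- 1
  }
  std <- structure(
    list(center = center, scale = scale, constant = constant,
         feature_names = colnames(X)),
    class = "std_features"
  )
  std$values <- apply_standardization(std, X)
  std
}

#' Apply stored standardization parameters to new cases
#'
#' @param std A `std_features` object from [standardize_features()].
#' @param X_new Matrix (or single row) of new feature values on the original
#'   scale.
#' @return Standardized matrix.
#' @export
apply_standardization <- function(std, X_new) {
  X_new <- if (is.null(dim(X_new))) matrix(X_new, nrow = 1) else as.matrix(X_new)
  if (ncol(X_new) != length(std$center)) {
    stop(sprintf("expected %d features, got %d", length(std$center), ncol(X_new)))
  }
  sweep(sweep(X_new, 2, std$center), 2, std$scale, `/`)
}
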