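#' Build the out-of-fold metadata table for one score component
#'
#' For every training case `n` and every learner `k`, fits learner `k` on all
#' cases except `n` (features re-standardized within the fold, penalty
#' selection re-run with the fold seed) and records the prediction for the
#' held-out case. The resulting N x K table is the "metadata" on which the
#' stacking weights are optimized and from which impactful training-set
#' outliers are identified.
#'
#' @param X Raw (unstandardized) feature matrix, N x P.
#' @param y Response vector (one principal-component score per case).
#' @param specs List of [learner_spec()] objects.
#' @param seed Integer seed; fold `n` uses `seed + n` for penalty selection.
#' @param penalty_mode `"per_fold"` re-selects each learner's penalty inside
#'   every fold (the normative, slower route); `"fixed"` selects penalties
#'   once on the full set and reuses them in the folds (approximate).
#' @param n_grid Penalty-grid size for [select_penalty()].
#' @param select_folds Internal CV folds for penalty selection.
#' @param case_ids Optional case identifiers.
#' @return An object of class `metadata_table`: `z` (N x K), `y`,
#'   `case_ids`, `learner_labels`.
#' @export
build_metadata <- function(X, y, specs, seed = 1,
                           penalty_mode = c("per_fold", "fixed"),
                           n_grid = 20, select_folds = 5, case_ids = NULL) {
  penalty_mode <- match.arg(penalty_mode)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 cases for leave-one-out metadata")
  K <- length(specs)
  if (is.null(case_ids)) case_ids <- rownames(X)
  if (is.null(case_ids)) case_ids <- sprintf("case_%03d", seq_len(n))
  if (penalty_mode == "fixed") {
    std_all <- standardize_features(X)
    specs <- lapply(seq_len(K), function(k) {
      sp <- specs[[k]]
      if (sp$kind == "stepwise") return(sp)
      select_penalty(std_all$values, y, sp, n_folds = min(select_folds, n),
                     grid = penalty_grid(std_all$values, y, n_grid),
                     seed = seed + 17L * k)
    })
  }
  z <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    std <- suppressWarnings(standardize_features(Xtr))
    xs_new <- apply_standardization(std, X[i, ])
    grid <- if (penalty_mode == "per_fold") {
      penalty_grid(std$values, ytr, n_grid)
    } else NULL
    for (k in seq_len(K)) {
      fit <- tryCatch(
        if (penalty_mode == "per_fold") {
          fit_learner(std$values, ytr, specs[[k]], seed = seed + i,
                      grid = grid, n_folds = min(select_folds, n - 1))
        } else if (specs[[k]]$kind == "stepwise") {
          fit_stepwise(std$values, ytr, specs[[k]]$p_enter)
        } else {
          fit_penalized(std$values, ytr, specs[[k]])
        },
        error = function(e) {
          stop(sprintf("metadata fit failed for case %d, learner %d (%s): %s",
                       i, k, specs[[k]]$label, conditionMessage(e)))
        }
      )
      z[i, k] <- predict(fit, xs_new)
    }
  }
  structure(
    list(z = z, y = y, case_ids = case_ids,
         learner_labels = vapply(specs, `[[`, character(1), "label")),
    class = "metadata_table"
  )
}

#' Optimize non-negative stacking weights on a metadata table
#'
#' Solves `min_a sum_n (y_n - sum_k a_k z_kn)^2` subject to `a_k >= 0` by
#' exact non-negative least squares ([nnls_fit()]). Because the feasible set
#' contains every unit vector, the optimized ensemble's internal
#' cross-validation error can never exceed that of any individual learner.
#' The weights are not constrained to sum to 1.
#'
#' @param meta A [build_metadata()] result.
#' @return Numeric vector of K non-negative weights.
#' @export
optimize_stack_weights <- function(meta) {
  Z <- meta$z
  if (!all(is.finite(Z))) stop("metadata table contains non-finite values")
  if (all(Z == 0)) {
    warning("metadata table is identically zero; returning zero weights")
    return(numeric(ncol(Z)))
  }
  nnls_fit(Z, meta$y)
}

#' Per-case median cross-validated wRMSE profile
#'
#' For every case and learner, the leave-one-out predicted scores (one per
#' retained component) are decoded into a DVH and scored against the clinical
#' curve with [wrmse()]; the profile is the per-case median over learners.
#' Cases with a high profile value are those that no learner can predict from
#' the remaining cohort — the operational signature of an outlier.
#'
#' @param metas List of `metadata_table`s, one per score component, matching
#'   case sets.
#' @param basis The cohort [fit_dvh_basis()].
#' @param dvhs List of clinical [dvh_curve()]s in case order.
#' @param scheme [weight_scheme()] used for the per-case error.
#' @return Named numeric vector of per-case median wRMSE values.
#' @export
case_wrmse_profile <- function(metas, basis,
                               dvhs, scheme = weight_scheme("linear_relative")) {
  if (length(metas) != basis$n_pc) {
    stop(sprintf("need metadata for all %d components, got %d",
                 basis$n_pc, length(metas)))
  }
  n <- nrow(metas[[1]]$z)
  K <- ncol(metas[[1]]$z)
  for (m in metas) {
    if (nrow(m$z) != n || ncol(m$z) != K ||
        !identical(m$case_ids, metas[[1]]$case_ids)) {
      stop("metadata tables disagree on cases or learners")
    }
  }
  profile <- numeric(n)
  for (i in seq_len(n)) {
    errs <- vapply(seq_len(K), function(k) {
      scores <- vapply(metas, function(m) m$z[i, k], numeric(1))
      wrmse(dvhs[[i]], decode_dvh(scores, basis), scheme)
    }, numeric(1))
    profile[i] <- stats::median(errs)
  }
  names(profile) <- metas[[1]]$case_ids
  profile
}

#' Drop the highest-error fraction of training cases
#'
#' Removes the `floor(s_percent/100 * N)` cases with the largest profile
#' values (ties resolved by removing the lower case index first).
#'
#' @param profile Per-case error profile from [case_wrmse_profile()].
#' @param s_percent Percentage of cases to drop, in `[0, 100)`; default 10.
#' @return List with `retained` (sorted indices kept), `removed` (indices
#'   dropped) and `report` (data frame of removed case ids and profile
#'   values, highest first).
#' @export
filter_cases <- function(profile, s_percent = 10) {
  if (s_percent < 0 || s_percent >= 100) {
    stop("s_percent must lie in [0, 100)")
  }
  n <- length(profile)
  n_remove <- floor(s_percent / 100 * n)
  ord <- order(-profile, seq_len(n))
  removed <- sort(ord[seq_len(n_remove)])
  ids <- names(profile)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  report <- data.frame(
    case_id = ids[ord[seq_len(n_remove)]],
    wrmse = unname(profile[ord[seq_len(n_remove)]]),
    stringsAsFactors = FALSE
  )
  list(retained = setdiff(seq_len(n), removed), removed = removed,
       report = report)
}

#' Configuration for ensemble training
#'
#' The defaults reproduce the reference configuration: nine base learners
#' (stepwise, ridge, lasso, six elastic-net ratios), three retained DVH
#' components, 10% case filtering, leave-one-out metadata with per-fold
#' penalty re-selection, and linear-relative error weighting.
#'
#' @param specs Learner bank.
#' @param n_pc Retained DVH principal components.
#' @param s_percent Filtering percentage.
#' @param scheme [weight_scheme()] for the filter profile.
#' @param penalty_mode `"per_fold"` (normative) or `"fixed"` (fast,
#'   approximate): see [build_metadata()].
#' @param n_grid Penalty-grid size.
#' @param select_folds Internal CV folds for penalty selection.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(specs = default_learner_specs(), n_pc = 3,
                            s_percent = 10,
                            scheme = weight_scheme("linear_relative"),
                            penalty_mode = c("per_fold", "fixed"),
                            n_grid = 20, select_folds = 5) {
  structure(list(specs = specs, n_pc = n_pc, s_percent = s_percent,
                 scheme = scheme, penalty_mode = match.arg(penalty_mode),
                 n_grid = n_grid, select_folds = select_folds),
            class = "ensemble_config")
}

#' Train the stacked DVH-prediction ensemble
#'
#' The full training workflow: fit the DVH principal-component basis on the
#' training cohort; encode every clinical DVH to scores; build leave-one-out
#' metadata for each component; score every case by its median
#' cross-validated wRMSE and drop the worst `s_percent`; then, on the
#' retained cases, rebuild the metadata, optimize non-negative stacking
#' weights per component, and refit every learner on the full retained set.
#' The basis is fitted once on the unfiltered cohort and kept, so filter
#' scores and downstream encodings stay comparable.
#'
#' @param features Raw N x P feature matrix.
#' @param dvhs List of clinical [dvh_curve()]s, one per case.
#' @param config An [ensemble_config()].
#' @param seed Integer seed driving penalty-selection folds.
#' @param case_ids Optional case identifiers.
#' @return An object of class `stacked_ensemble`: `learners` (per component,
#'   a list of K `base_learner_model`s), `alpha` (K x n_pc weight matrix),
#'   `basis`, `std` (feature standardization of the retained set), `config`,
#'   `filter_report`, `retained_ids`, `seed`.
#' @export
train_ensemble <- function(features, dvhs, config = ensemble_config(),
                           seed = 1, case_ids = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  K <- length(config$specs)
  if (length(dvhs) != n) stop("features and dvhs disagree on case count")
  if (is.null(case_ids)) case_ids <- rownames(features)
  if (is.null(case_ids)) case_ids <- sprintf("case_%03d", seq_len(n))
  rownames(features) <- case_ids
  n_retained <- n - floor(config$s_percent / 100 * n)
  if (n_retained < K + 2) {
    stop(sprintf("only %d cases would be retained after filtering; need at least %d",
                 n_retained, K + 2))
  }

  basis <- fit_dvh_basis(dvhs, n_pc = config$n_pc)
  Y <- t(vapply(dvhs, encode_dvh, numeric(config$n_pc), basis = basis))
  if (config$n_pc == 1) Y <- matrix(Y, ncol = 1)

  metas <- lapply(seq_len(config$n_pc), function(cc) {
    build_metadata(features, Y[, cc], config$specs,
                   seed = seed + 1000L * cc,
                   penalty_mode = config$penalty_mode,
                   n_grid = config$n_grid,
                   select_folds = config$select_folds, case_ids = case_ids)
  })
  profile <- case_wrmse_profile(metas, basis, dvhs, config$scheme)
  filt <- filter_cases(profile, config$s_percent)
  keep <- filt$retained
  Xr <- features[keep, , drop = FALSE]
  Yr <- Y[keep, , drop = FALSE]
  dropped_any <- length(filt$removed) > 0
  metas_r <- if (dropped_any) {
    lapply(seq_len(config$n_pc), function(cc) {
      build_metadata(Xr, Yr[, cc], config$specs,
                     seed = seed + 1000L * cc,
                     penalty_mode = config$penalty_mode,
                     n_grid = config$n_grid,
                     select_folds = config$select_folds,
                     case_ids = case_ids[keep])
    })
  } else metas

  std <- suppressWarnings(standardize_features(Xr))
  alpha <- matrix(0, K, config$n_pc,
                  dimnames = list(vapply(config$specs, `[[`, character(1),
                                         "label"),
                                  paste0("pcs", seq_len(config$n_pc))))
  learners <- vector("list", config$n_pc)
  for (cc in seq_len(config$n_pc)) {
    alpha[, cc] <- optimize_stack_weights(metas_r[[cc]])
    grid <- penalty_grid(std$values, Yr[, cc], config$n_grid)
    learners[[cc]] <- lapply(config$specs, function(sp) {
      fit_learner(std$values, Yr[, cc], sp, seed = seed + 1000L * cc,
                  grid = grid,
                  n_folds = min(config$select_folds, nrow(Xr)))
    })
  }
  structure(
    list(learners = learners, alpha = alpha, basis = basis, std = std,
         config = config, filter_report = filt$report,
         retained_ids = case_ids[keep], seed = seed),
    class = "stacked_ensemble"
  )
}

#' @export
print.stacked_ensemble <- function(x, ...) {
  cat(sprintf(paste0(
    "<stacked_ensemble> %d learners x %d components, %d cases retained",
    " (%d filtered)\n"),
    nrow(x$alpha), ncol(x$alpha), length(x$retained_ids),
    nrow(x$filter_report)))
  cat("weight sums per component:",
      paste(sprintf("%.3f", colSums(x$alpha)), collapse = ", "), "\n")
  invisible(x)
}

#' Predict principal-component scores for new cases
#'
#' @param model A `stacked_ensemble` or `single_dvh_model`.
#' @param X_new Matrix (or single row) of raw features.
#' @return N x n_pc matrix of predicted scores.
#' @export
predict_pcs <- function(model, X_new) {
  UseMethod("predict_pcs")
}

#' @export
predict_pcs.stacked_ensemble <- function(model, X_new) {
  Xs <- apply_standardization(model$std, X_new)
  n_pc <- ncol(model$alpha)
  out <- matrix(0, nrow(Xs), n_pc)
  for (cc in seq_len(n_pc)) {
    Z <- vapply(model$learners[[cc]], predict, numeric(nrow(Xs)),
                newdata = Xs)
    if (nrow(Xs) == 1) Z <- matrix(Z, nrow = 1)
    out[, cc] <- Z %*% model$alpha[, cc]
  }
  out
}

#' Predict DVH curves for new cases
#'
#' Combines the base-learner score predictions with the stacking weights and
#' decodes through the stored basis into valid DVH curves.
#'
#' @param model A `stacked_ensemble` or `single_dvh_model`.
#' @param X_new Matrix (or single row) of raw features.
#' @return A single [dvh_curve()] for one case, otherwise a list of curves.
#' @export
predict_dvh <- function(model, X_new) {
  pcs <- predict_pcs(model, X_new)
  basis <- model$basis
  curves <- lapply(seq_len(nrow(pcs)), function(i) decode_dvh(pcs[i, ], basis))
  if (length(curves) == 1) curves[[1]] else curves
}

#' Train a single base learner as a standalone DVH model
#'
#' Fits one learner per retained component on the full training set (no
#' metadata, no filtering) — the baseline against which the stacked ensemble
#' is compared.
#'
#' @param features Raw feature matrix.
#' @param dvhs Clinical DVH curves.
#' @param spec A [learner_spec()].
#' @param n_pc Retained components.
#' @param seed Seed for penalty selection.
#' @param n_grid Penalty-grid size.
#' @param basis Optional pre-fitted [fit_dvh_basis()] (reused so competing
#'   models share a representation).
#' @return An object of class `single_dvh_model`.
#' @export
train_individual <- function(features, dvhs, spec, n_pc = 3, seed = 1,
                             n_grid = 20, basis = NULL) {
  features <- as.matrix(features)
  if (is.null(basis)) basis <- fit_dvh_basis(dvhs, n_pc = n_pc)
  Y <- t(vapply(dvhs, encode_dvh, numeric(basis$n_pc), basis = basis))
  if (basis$n_pc == 1) Y <- matrix(Y, ncol = 1)
  std <- suppressWarnings(standardize_features(features))
  learners <- lapply(seq_len(basis$n_pc), function(cc) {
    fit_learner(std$values, Y[, cc], spec, seed = seed + 1000L * cc,
                grid = if (spec$kind == "stepwise") NULL
                       else penalty_grid(std$values, Y[, cc], n_grid))
  })
  structure(list(learners = learners, basis = basis, std = std, spec = spec),
            class = "single_dvh_model")
}

#' @export
predict_pcs.single_dvh_model <- function(model, X_new) {
  Xs <- apply_standardization(model$std, X_new)
  vapply(model$learners, predict, numeric(nrow(Xs)), newdata = Xs)
}

#' Validation-set error of a DVH model
#'
#' @param model Any model supporting [predict_dvh()].
#' @param features Validation feature matrix.
#' @param dvhs Validation clinical curves.
#' @param scheme [weight_scheme()].
#' @return Numeric vector of per-case wRMSE values.
#' @export
evaluate_model <- function(model, features, dvhs,
                           scheme = weight_scheme("linear_relative")) {
  pcs <- predict_pcs(model, as.matrix(features))
  vapply(seq_along(dvhs), function(i) {
    wrmse(dvhs[[i]], decode_dvh(pcs[i, ], model$basis), scheme)
  }, numeric(1))
}

#' Compare DVH models on a validation cohort
#'
#' Computes per-case wRMSE for every model, summary statistics, and paired
#' two-sided tests (Wilcoxon signed-rank and sign test) between the reference
#' model (by default the first, conventionally the ensemble) and every other
#' model.
#'
#' @param models Named list of fitted models ([train_ensemble()] /
#'   [train_individual()] results).
#' @param features Validation feature matrix.
#' @param dvhs Validation clinical curves.
#' @param scheme [weight_scheme()].
#' @param reference Name of the reference model; default the first.
#' @return List with `per_case` (cases x models wRMSE matrix), `summary`
#'   (mean/median per model) and `tests` (reference vs each model).
#' @export
compare_models <- function(models, features, dvhs,
                           scheme = weight_scheme("linear_relative"),
                           reference = names(models)[1]) {
  if (length(models) < 2) stop("need at least 2 models to compare")
  if (length(dvhs) < 5) stop("need at least 5 validation cases")
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste0("model_", seq_along(models))
  }
  per_case <- vapply(models, evaluate_model, numeric(length(dvhs)),
                     features = features, dvhs = dvhs, scheme = scheme)
  summary_df <- data.frame(
    model = colnames(per_case),
    mean_wrmse = colMeans(per_case),
    median_wrmse = apply(per_case, 2, stats::median),
    row.names = NULL, stringsAsFactors = FALSE
  )
  others <- setdiff(colnames(per_case), reference)
  tests <- do.call(rbind, lapply(others, function(m) {
    d <- per_case[, m] - per_case[, reference]
    if (all(d == 0)) {
      warning(sprintf("models '%s' and '%s' give identical errors", reference, m))
      wp <- 1
      sp <- NA_real_
    } else {
      wp <- suppressWarnings(
        stats::wilcox.test(per_case[, m], per_case[, reference],
                           paired = TRUE)$p.value)
      nz <- d[d != 0]
      sp <- stats::binom.test(sum(nz > 0), length(nz))$p.value
    }
    data.frame(model = m, mean_diff = mean(d), wilcoxon_p = wp, sign_p = sp,
               stringsAsFactors = FALSE)
  }))
  list(per_case = per_case, summary = summary_df, tests = tests,
       reference = reference)
}
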