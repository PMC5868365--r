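# Read a delimited table with explicit structural checks so malformed files
# fail with line numbers rather than silent coercion.
read_checked_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) < 2) stop(path, ": needs a header row and at least one case")
  bad <- which(nf != nf[1])
  if (length(bad) > 0) {
    stop(sprintf("%s: ragged row(s) at line %s (expected %d fields)",
                 path, paste(bad, collapse = ", "), nf[1]))
  }
  utils::read.csv(path, check.names = FALSE, colClasses = "character")
}

numeric_cols <- function(df, cols, path) {
  out <- matrix(NA_real_, nrow(df), length(cols))
  for (j in seq_along(cols)) {
    v <- suppressWarnings(as.numeric(df[[cols[j]]]))
    bad <- which(is.na(v) & !(df[[cols[j]]] %in% c("NA", "")))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric value in column '%s' at line %s",
                   path, cols[j], paste(bad + 1L, collapse = ", ")))
    }
    out[, j] <- v
  }
  colnames(out) <- cols
  out
}

#' Write / read a feature table
#'
#' Plain CSV, one row per case: `case_id` column followed by one named column
#' per anatomical feature.
#'
#' @param features N x P numeric matrix with column names.
#' @param case_ids Character vector of case identifiers.
#' @param path File path.
#' @return `read_feature_table()` returns a list with `features` (named
#'   matrix, case ids as rownames) and `case_ids`.
#' @export
write_feature_table <- function(features, case_ids, path) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  df <- data.frame(case_id = case_ids, features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read_checked_csv(path)
  if (!"case_id" %in% names(df)) stop(path, ": missing case_id column")
  feat_cols <- setdiff(names(df), "case_id")
  X <- numeric_cols(df, feat_cols, path)
  rownames(X) <- df$case_id
  list(features = X, case_ids = df$case_id)
}

#' Write / read a DVH table
#'
#' Plain CSV, one row per case: `case_id`, `prescription_dose`, then one
#' column per dose-grid point whose header is the dose value in Gy.
#'
#' @param dvhs List of [dvh_curve()]s on a common grid.
#' @param case_ids Case identifiers.
#' @param path File path.
#' @return `read_dvh_table()` returns a list with `dvhs` (list of curves)
#'   and `case_ids`.
#' @export
write_dvh_table <- function(dvhs, case_ids, path) {
  grid <- dvhs[[1]]$dose_grid
  V <- do.call(rbind, lapply(dvhs, `[[`, "volume_fraction"))
  df <- data.frame(
    case_id = case_ids,
    prescription_dose = vapply(dvhs, `[[`, numeric(1), "prescription_dose"),
    V, check.names = FALSE, stringsAsFactors = FALSE
  )
  names(df)[-(1:2)] <- format(grid, digits = 12, trim = TRUE,
                              scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dvh_table
#' @export
read_dvh_table <- function(path) {
  df <- read_checked_csv(path)
  need <- c("case_id", "prescription_dose")
  if (!all(need %in% names(df))) {
    stop(path, ": missing column(s) ", paste(setdiff(need, names(df)),
                                             collapse = ", "))
  }
  dose_cols <- setdiff(names(df), need)
  grid <- suppressWarnings(as.numeric(dose_cols))
  if (anyNA(grid)) stop(path, ": non-numeric dose value in header")
  V <- numeric_cols(df, dose_cols, path)
  rx <- as.numeric(numeric_cols(df, "prescription_dose", path))
  dvhs <- lapply(seq_len(nrow(V)), function(i) {
    dvh_curve(grid, V[i, ], rx[i])
  })
  list(dvhs = dvhs, case_ids = df$case_id)
}

#' Write / read a case-label file
#'
#' Two-column CSV (`case_id`, `label`) recording which cohort cases are
#' injected outliers.
#'
#' @param labels Character labels per case.
#' @param case_ids Case identifiers.
#' @param path File path.
#' @return `read_labels()` returns a named character vector.
#' @export
write_labels <- function(labels, case_ids, path) {
  utils::write.csv(data.frame(case_id = case_ids, label = labels,
                              stringsAsFactors = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read_checked_csv(path)
  if (!all(c("case_id", "label") %in% names(df))) {
    stop(path, ": expected columns case_id, label")
  }
  stats::setNames(df$label, df$case_id)
}

#' Check that two files describe the same cases
#'
#' @param ids_a,ids_b Case-id vectors.
#' @param what_a,what_b Labels used in the error message.
#' @return Invisibly `TRUE`; errors naming the offending ids otherwise.
#' @export
check_case_ids <- function(ids_a, ids_b, what_a = "features", what_b = "dvhs") {
  only_a <- setdiff(ids_a, ids_b)
  only_b <- setdiff(ids_b, ids_a)
  if (length(only_a) > 0 || length(only_b) > 0) {
    stop(sprintf(
      "case-id mismatch: %s only in %s; %s only in %s",
      if (length(only_a)) paste(only_a, collapse = ", ") else "(none)", what_a,
      if (length(only_b)) paste(only_b, collapse = ", ") else "(none)", what_b))
  }
  invisible(TRUE)
}

#' Write a synthetic cohort as the delimited files the trainer consumes
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written (`features`, `dvhs`, `labels`).
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    features = file.path(dir, paste0(prefix, "_features.csv")),
    dvhs = file.path(dir, paste0(prefix, "_dvh.csv")),
    labels = file.path(dir, paste0(prefix, "_labels.csv"))
  )
  write_feature_table(cohort$features, cohort$case_ids, paths$features)
  write_dvh_table(cohort$dvhs, cohort$case_ids, paths$dvhs)
  write_labels(cohort$labels, cohort$case_ids, paths$labels)
  invisible(paths)
}

#' Serialize a DVH principal-component basis as delimited text
#'
#' The matrix file holds the mean curve (first row) and one row per
#' component; a JSON sidecar (`<path>.json`) records the dose grid, retained
#' component count, explained variance and prescription dose.
#'
#' @param basis A [fit_dvh_basis()] result.
#' @param path Path of the delimited matrix file.
#' @return `read_dvh_basis()` returns the `dvh_basis`.
#' @export
write_dvh_basis <- function(basis, path) {
  M <- rbind(basis$mean_curve, basis$components)
  rownames(M) <- c("mean", paste0("pc", seq_len(basis$n_pc)))
  utils::write.table(M, path, sep = ",", col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(dose_grid = basis$dose_grid, n_pc = basis$n_pc,
         explained_variance = basis$explained_variance,
         total_variance = basis$total_variance,
         prescription_dose = basis$prescription_dose),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dvh_basis
#' @export
read_dvh_basis <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  M <- as.matrix(utils::read.table(path, sep = ",", row.names = 1))
  structure(
    list(dose_grid = meta$dose_grid, mean_curve = unname(M["mean", ]),
         components = unname(M[-1, , drop = FALSE]),
         explained_variance = meta$explained_variance,
         total_variance = meta$total_variance, n_pc = meta$n_pc,
         prescription_dose = meta$prescription_dose),
    class = "dvh_basis"
  )
}

spec_to_list <- function(sp) {
  sp[!vapply(sp, is.null, logical(1))]
}

list_to_spec <- function(l) {
  learner_spec(l$kind, lambda1 = l$lambda1, lambda2 = l$lambda2,
               ratio = l$ratio, p_enter = l$p_enter, label = l$label)
}

#' Serialize a trained stacked ensemble to JSON
#'
#' The JSON document is human-auditable: per-component stacking weights,
#' every base learner's spec, intercept and coefficients, the feature
#' standardization, the DVH basis and the filter report.
#'
#' @param model A [train_ensemble()] result.
#' @param path Output path.
#' @return `read_ensemble_json()` returns the reconstructed
#'   `stacked_ensemble`.
#' @export
write_ensemble_json <- function(model, path) {
  doc <- list(
    format = "dvhstack_ensemble_v1",
    seed = model$seed,
    alpha = as.numeric(model$alpha),  # column-major, K x n_pc
    n_learners = nrow(model$alpha),
    learner_labels = rownames(model$alpha),
    learners = lapply(model$learners, function(bank) {
      lapply(bank, function(m) {
        list(spec = spec_to_list(m$spec), intercept = m$intercept,
             coefficients = m$coefficients,
             selected_features = m$selected_features)
      })
    }),
    standardization = list(center = model$std$center, scale = model$std$scale,
                           constant = model$std$constant,
                           feature_names = model$std$feature_names),
    basis = list(dose_grid = model$basis$dose_grid,
                 mean_curve = model$basis$mean_curve,
                 components = as.numeric(t(model$basis$components)),
                 explained_variance = model$basis$explained_variance,
                 total_variance = model$basis$total_variance,
                 n_pc = model$basis$n_pc,
                 prescription_dose = model$basis$prescription_dose),
    config = list(s_percent = model$config$s_percent,
                  n_pc = model$config$n_pc,
                  penalty_mode = model$config$penalty_mode,
                  n_grid = model$config$n_grid,
                  select_folds = model$config$select_folds,
                  scheme = unclass(model$config$scheme)),
    filter_report = list(case_id = model$filter_report$case_id,
                         wrmse = model$filter_report$wrmse),
    retained_ids = model$retained_ids
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ensemble_json
#' @export
read_ensemble_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$format, "dvhstack_ensemble_v1")) {
    stop(path, ": not a dvhstack ensemble document")
  }
  n_pc <- as.integer(doc$basis$n_pc)
  alpha <- matrix(as.numeric(doc$alpha), nrow = doc$n_learners,
                  dimnames = list(doc$learner_labels,
                                  paste0("pcs", seq_len(n_pc))))
  learners <- lapply(doc$learners, function(bank) {
    lapply(bank, function(m) {
      new_base_learner(list_to_spec(m$spec), m$intercept,
                       as.numeric(m$coefficients),
                       as.integer(unlist(m$selected_features)),
                       doc$standardization$feature_names)
    })
  })
  std <- structure(
    list(center = doc$standardization$center,
         scale = doc$standardization$scale,
         constant = doc$standardization$constant,
         feature_names = doc$standardization$feature_names),
    class = "std_features"
  )
  basis <- structure(
    list(dose_grid = doc$basis$dose_grid, mean_curve = doc$basis$mean_curve,
         components = matrix(as.numeric(doc$basis$components), nrow = n_pc,
                             byrow = TRUE),
         explained_variance = doc$basis$explained_variance,
         total_variance = doc$basis$total_variance, n_pc = n_pc,
         prescription_dose = doc$basis$prescription_dose),
    class = "dvh_basis"
  )
  scheme <- structure(doc$config$scheme, class = "weight_scheme")
  cfg <- ensemble_config(
    specs = lapply(doc$learners[[1]], function(m) list_to_spec(m$spec)),
    n_pc = n_pc, s_percent = doc$config$s_percent, scheme = scheme,
    penalty_mode = doc$config$penalty_mode, n_grid = doc$config$n_grid,
    select_folds = doc$config$select_folds
  )
  report <- data.frame(
    case_id = as.character(unlist(doc$filter_report$case_id)),
    wrmse = as.numeric(unlist(doc$filter_report$wrmse)),
    stringsAsFactors = FALSE
  )
  structure(
    list(learners = learners, alpha = alpha, basis = basis, std = std,
         config = cfg, filter_report = report,
         retained_ids = doc$retained_ids, seed = doc$seed),
    class = "stacked_ensemble"
  )
}
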