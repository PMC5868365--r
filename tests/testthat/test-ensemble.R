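make_meta <- function(z, y, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("case_%03d", seq_len(nrow(z)))
  structure(list(z = z, y = y, case_ids = ids,
                 learner_labels = paste0("L", seq_len(ncol(z)))),
            class = "metadata_table")
}

test_that("stack weights lock onto a perfect predictor and stay non-negative", {
  withr::local_seed(21)
  y <- stats::rnorm(30)
  Z <- cbind(y, matrix(stats::rnorm(30 * 4), 30, 4))
  a <- optimize_stack_weights(make_meta(Z, y))
  expect_equal(a, c(1, 0, 0, 0, 0), tolerance = 1e-8)
  expect_true(all(a >= 0))
  expect_warning(a0 <- optimize_stack_weights(make_meta(matrix(0, 5, 3),
                                                        stats::rnorm(5))),
                 "zero")
  expect_identical(a0, numeric(3))
})

test_that("per-case profile reduces to the median over learner errors", {
  curves <- fixture_curves(10, seed = 41)
  basis <- fit_dvh_basis(curves, 3)
  Y <- t(vapply(curves, encode_dvh, numeric(3), basis = basis))
  withr::local_seed(42)
  metas <- lapply(1:3, function(cc) {
    make_meta(matrix(Y[, cc], 10, 3) + matrix(stats::rnorm(30, 0, 0.03), 10, 3),
              Y[, cc])
  })
  sch <- weight_scheme("linear_relative")
  prof <- case_wrmse_profile(metas, basis, curves, sch)
  # naive per-case loop oracle
  naive <- vapply(1:10, function(i) {
    stats::median(vapply(1:3, function(k) {
      wrmse(curves[[i]],
            decode_dvh(c(metas[[1]]$z[i, k], metas[[2]]$z[i, k],
                         metas[[3]]$z[i, k]), basis), sch)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(prof), naive, tolerance = 1e-12)

  # learner predictions equal to the truth leave only decode residual
  metas_exact <- lapply(1:3, function(cc) make_meta(matrix(Y[, cc], 10, 3),
                                                    Y[, cc]))
  prof0 <- case_wrmse_profile(metas_exact, basis, curves, sch)
  expect_lt(max(prof0), 1e-10)
  expect_error(case_wrmse_profile(metas[1:2], basis, curves, sch), "component")
})

test_that("filtering obeys the floor rule, tie-breaks and monotonicity", {
  prof <- c(5, 1, 3, 2, 4) / 10
  names(prof) <- paste0("c", 1:5)
  expect_identical(filter_cases(prof, 0)$removed, integer(0))
  f <- filter_cases(prof, 40)  # floor(0.4*5) = 2
  expect_identical(f$removed, c(1L, 5L))
  expect_identical(f$report$case_id, c("c1", "c5"))
  # N=50, s=10 removes exactly 5
  withr::local_seed(50)
  p50 <- stats::runif(50)
  expect_length(filter_cases(p50, 10)$removed, 5L)
  # ties: lower index removed first
  ptie <- c(1, 1, 1, 0.5)
  expect_identical(filter_cases(ptie, 25)$removed, 1L)
  # constructed separation: 10 planted at 10x the rest
  p100 <- c(rep(0.01, 90), rep(0.1, 10)) ; names(p100) <- 1:100
  expect_identical(filter_cases(p100, 10)$removed, 91:100 + 0L)
  # monotone nesting in s
  prev <- integer(0)
  for (s in c(0, 10, 20, 40, 60)) {
    cur <- filter_cases(p50, s)$removed
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_error(filter_cases(p50, 100), "s_percent")
})

test_that("a clean noiseless cohort is recovered almost exactly", {
  cfg <- cohort_config(n_cases = 40, noise_sd = c(0, 0, 0))
  co <- generate_cohort(cfg, seed = 31)
  ens <- train_ensemble(co$features, co$dvhs,
                        ensemble_config(penalty_mode = "fixed", n_grid = 8,
                                        s_percent = 0),
                        seed = 31)
  val <- generate_cohort(cfg, seed = 32)
  expect_lt(mean(evaluate_model(ens, val$features, val$dvhs)), 1e-3)
})

test_that("training is deterministic: identical seeds give identical JSON", {
  co <- generate_cohort(cohort_config(n_cases = 30), seed = 61)
  cfg <- ensemble_config(penalty_mode = "fixed", n_grid = 6)
  e1 <- train_ensemble(co$features, co$dvhs, cfg, seed = 9)
  e2 <- train_ensemble(co$features, co$dvhs, cfg, seed = 9)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_ensemble_json(e1, f1); write_ensemble_json(e2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ensemble prediction is the weighted learner combination", {
  withr::local_seed(71)
  curves <- fixture_curves(12, seed = 71)
  basis <- fit_dvh_basis(curves, 3)
  X <- matrix(stats::rnorm(12 * 4), 12, 4)
  std <- standardize_features(X)
  # hand-built two-learner ensemble
  mk <- function(int, beta) {
    dvhstack:::new_base_learner(learner_spec("ridge", lambda2 = 1), int, beta,
                                which(beta != 0), NULL)
  }
  m1 <- mk(0.1, c(0.2, 0, -0.1, 0)); m2 <- mk(-0.05, c(0, 0.3, 0, 0.1))
  ens <- structure(list(
    learners = list(list(m1, m2), list(m1, m2), list(m1, m2)),
    alpha = matrix(c(0.7, 0.4), 2, 3,
                   dimnames = list(c("a", "b"), paste0("pcs", 1:3))),
    basis = basis, std = std), class = "stacked_ensemble")
  xnew <- stats::rnorm(4)
  xs <- as.numeric(apply_standardization(std, xnew))
  by_hand <- 0.7 * (0.1 + sum(xs * m1$coefficients)) +
             0.4 * (-0.05 + sum(xs * m2$coefficients))
  expect_equal(unname(predict_pcs(ens, xnew)[1, ]), rep(by_hand, 3),
               tolerance = 1e-12)
  # all weight on one learner reproduces that learner; zero weight, the mean
  ens$alpha <- matrix(c(1, 0), 2, 3)
  expect_equal(unname(predict_pcs(ens, xnew)[1, 1]),
               0.1 + sum(xs * m1$coefficients))
  ens$alpha <- matrix(0, 2, 3)
  cv <- predict_dvh(ens, xnew)
  expect_equal(cv$volume_fraction, postprocess_volume(basis$mean_curve))
})

test_that("with no filtering and one learner the ensemble is a scaled learner", {
  co <- generate_cohort(cohort_config(n_cases = 25), seed = 81)
  cfg <- ensemble_config(specs = list(learner_spec("ridge", lambda2 = 3)),
                         s_percent = 0)
  ens <- train_ensemble(co$features, co$dvhs, cfg, seed = 5)
  expect_true(all(ens$alpha >= 0))
  single <- train_individual(co$features, co$dvhs,
                             learner_spec("ridge", lambda2 = 3),
                             basis = ens$basis)
  xnew <- co$features[3, ]
  for (cc in 1:3) {
    a <- ens$alpha[1, cc]
    lp <- predict(ens$learners[[cc]][[1]],
                  apply_standardization(ens$std, xnew))
    expect_equal(unname(predict_pcs(ens, xnew)[1, cc]), unname(a * lp),
                 tolerance = 1e-10)
  }
  expect_equal(single$learners[[1]]$coefficients,
               ens$learners[[1]][[1]]$coefficients, tolerance = 1e-10)
})

test_that("train_ensemble rejects cohorts that filter below the learner count", {
  co <- generate_cohort(cohort_config(n_cases = 12), seed = 91)
  cfg <- ensemble_config(penalty_mode = "fixed", n_grid = 5, s_percent = 20)
  expect_error(train_ensemble(co$features, co$dvhs, cfg, seed = 1),
               "retained")
})

test_that("model comparison summaries and paired tests are correct", {
  curves <- fixture_curves(8, seed = 55)
  basis <- fit_dvh_basis(curves, 3)
  X <- withr::with_seed(56, matrix(stats::rnorm(8 * 3), 8, 3))
  spec <- learner_spec("ridge", lambda2 = 1)
  m1 <- train_individual(X, curves, spec, basis = basis)
  expect_warning(
    cmp_same <- compare_models(list(a = m1, b = m1), X, curves),
    "identical")
  expect_equal(cmp_same$tests$mean_diff, 0)
  expect_equal(cmp_same$tests$wilcoxon_p, 1)

  # doubled residual curves: model c is worse on every case
  m2 <- m1
  m2$learners <- lapply(m2$learners, function(l) {
    l$coefficients <- l$coefficients * 3; l$intercept <- l$intercept + 0.2; l
  })
  cmp <- compare_models(list(a = m1, c = m2), X, curves)
  expect_true(all(cmp$per_case[, "c"] >= cmp$per_case[, "a"]))
  expect_gt(cmp$tests$mean_diff, 0)

  # reported paired tests match textbook computations on the observed
  # differences: exact sign-flip enumeration (Wilcoxon) and the binomial
  # two-sided sign test
  d <- cmp$per_case[, "c"] - cmp$per_case[, "a"]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  Wdist <- as.numeric(signs %*% r)
  p_wilcox <- mean(abs(Wdist - sum(r) / 2) >= abs(W - sum(r) / 2))
  expect_equal(cmp$tests$wilcoxon_p, p_wilcox, tolerance = 1e-12)
  k <- sum(d > 0); n <- sum(d != 0)
  p_sign <- min(1, 2 * min(stats::pbinom(k, n, 0.5),
                           1 - stats::pbinom(k - 1, n, 0.5)))
  expect_equal(cmp$tests$sign_p, p_sign, tolerance = 1e-12)
})
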