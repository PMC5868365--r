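test_that("dvh_curve enforces its invariants", {
  g <- make_dose_grid(78)
  v <- postprocess_volume(seq(1, 0, length.out = length(g)))
  expect_s3_class(dvh_curve(g, v, 78), "dvh_curve")
  expect_error(dvh_curve(g + 1, v, 78), "start at 0")
  expect_error(dvh_curve(g, v * 0.9, 78), "at 0 Gy must equal 1")
  expect_error(dvh_curve(g, v * 2, 78), "\\[0, 1\\]")
  vv <- v; vv[5] <- vv[3]  # bump upward
  expect_error(dvh_curve(g, vv, 78), "non-increasing")
})

test_that("basis fitting handles degenerate cohorts", {
  g <- make_dose_grid(70, n_bins = 41)
  v <- postprocess_volume(1 - g / max(g))  # strictly decreasing everywhere
  same <- replicate(10, dvh_curve(g, v, 70), simplify = FALSE)
  b <- fit_dvh_basis(same, n_pc = 1)
  expect_equal(b$mean_curve, v)
  expect_equal(b$explained_variance[1], 0)

  # rank-1 family: mean + t*u reproduces u (up to sign) and reconstructs
  u <- sin(pi * g / max(g)); u <- u / sqrt(sum(u^2))
  ts <- seq(-0.05, 0.05, length.out = 8)
  curves <- lapply(ts, function(t) {
    dvh_curve(g, postprocess_volume(v + t * u), 70, validate = FALSE)
  })
  b1 <- fit_dvh_basis(curves, n_pc = 1)
  expect_lt(min(sum((b1$components[1, ] - u)^2),
                sum((b1$components[1, ] + u)^2)), 1e-18)
  s <- encode_dvh(curves[[2]], b1)
  rec <- decode_dvh(s, b1)
  expect_lt(max(abs(rec$volume_fraction - curves[[2]]$volume_fraction)), 1e-10)

  expect_error(fit_dvh_basis(same[1:1], n_pc = 1), "at least")
  other <- dvh_curve(make_dose_grid(70, n_bins = 21),
                     postprocess_volume(1 - seq(0, 1, length.out = 21)), 70)
  expect_error(fit_dvh_basis(c(same, list(other))), "grids do not match")
})

test_that("explained variance matches a full eigendecomposition oracle", {
  curves <- fixture_curves(30, rank = 3, seed = 11, noise = 0.002)
  b <- fit_dvh_basis(curves, n_pc = 3)
  V <- do.call(rbind, lapply(curves, `[[`, "volume_fraction"))
  ev <- eigen(stats::cov(V), symmetric = TRUE)$values
  expect_equal(b$explained_variance, ev[1:3], tolerance = 1e-10)
  # non-increasing, and summing over all components gives total variance
  expect_true(all(diff(b$explained_variance) <= 1e-15))
  expect_equal(b$total_variance, sum(ev), tolerance = 1e-10)
})

test_that("encode is an orthonormal projection", {
  curves <- fixture_curves(25, seed = 3)
  b <- fit_dvh_basis(curves, n_pc = 3)
  mean_curve <- dvh_curve(b$dose_grid, postprocess_volume(b$mean_curve),
                          78, validate = FALSE)
  expect_equal(encode_dvh(mean_curve, b), rep(0, 3), tolerance = 1e-9)
  shifted <- dvh_curve(b$dose_grid, b$mean_curve + 2.5 * b$components[1, ],
                       78, validate = FALSE)
  expect_equal(encode_dvh(shifted, b), c(2.5, 0, 0), tolerance = 1e-8)
  # naive inner-product loop oracle on an arbitrary curve
  cv <- curves[[7]]
  naive <- vapply(1:3, function(j) {
    sum((cv$volume_fraction - b$mean_curve) * b$components[j, ])
  }, numeric(1))
  expect_equal(encode_dvh(cv, b), naive, tolerance = 1e-12)
})

test_that("decode always yields a valid curve and round-trips in-span input", {
  curves <- fixture_curves(25, seed = 5)
  b <- fit_dvh_basis(curves, n_pc = 3)
  # encode-decode round trip of an in-span monotone curve
  rt <- decode_dvh(encode_dvh(curves[[3]], b), b)
  expect_lt(max(abs(rt$volume_fraction - curves[[3]]$volume_fraction)), 1e-10)
  # second round trip changes nothing (idempotence on the basis span)
  rt2 <- decode_dvh(encode_dvh(rt, b), b)
  expect_lt(max(abs(rt2$volume_fraction - rt$volume_fraction)), 1e-10)
  # wild scores still decode to valid curves
  withr::with_seed(8, {
    for (i in 1:50) {
      cv <- decode_dvh(stats::rnorm(3, 0, 5), b)
      expect_true(all(cv$volume_fraction >= 0 & cv$volume_fraction <= 1))
      expect_true(all(diff(cv$volume_fraction) <= 0))
      expect_identical(cv$volume_fraction[1], 1)
    }
  })
  expect_error(decode_dvh(c(1, 2), b), "length")
})

test_that("weight vectors implement the three schemes", {
  curves <- fixture_curves(10, seed = 2)
  truth <- curves[[1]]
  rx <- truth$prescription_dose
  w_lin <- make_weight_vector(weight_scheme("linear_relative"), truth)
  expect_equal(w_lin[1], 50)
  expect_equal(w_lin[which.min(abs(truth$dose_grid - rx))], 100)
  expect_equal(w_lin[length(w_lin)], 100)  # flat beyond prescription
  expect_equal(make_weight_vector(weight_scheme("constant"), truth),
               rep(1, length(truth$dose_grid)))
  w_g <- make_weight_vector(weight_scheme("gaussian_median"), truth)
  d50 <- median_dose(truth)
  at <- function(d) exp(-(d - d50)^2 / 8)
  expect_equal(max(w_g), at(truth$dose_grid[which.max(w_g)]))
  # value two SD (4 Gy... SD is 2 Gy) away drops by exp(-1/2) at 2 Gy offset
  i0 <- which.min(abs(truth$dose_grid - d50))
  i2 <- which.min(abs(truth$dose_grid - (d50 + 2)))
  expect_equal(w_g[i2] / w_g[i0],
               at(truth$dose_grid[i2]) / at(truth$dose_grid[i0]),
               tolerance = 1e-12)
  expect_true(all(w_g > 0))
})

test_that("median dose interpolates the 0.5 crossing and errors when absent", {
  g <- c(0, 10, 20, 30)
  cv <- dvh_curve(g, c(1, 0.8, 0.4, 0.1), 30)
  # crossing between 10 and 20: 0.8 -> 0.4, hits 0.5 at 10 + 10*(0.3/0.4)
  expect_equal(median_dose(cv), 17.5)
  high <- dvh_curve(g, c(1, 0.9, 0.8, 0.7), 30)
  expect_error(median_dose(high), "median dose undefined")
})

test_that("wrmse matches hand evaluation and behaves as a weighted norm", {
  g <- c(0, 40)
  t2 <- dvh_curve(g, c(1, 0.5), 40)
  p2 <- dvh_curve(g, c(1 - 0.3, 0.5), 40, validate = FALSE)
  p2$volume_fraction <- c(0.7, 0.5)
  # raw weights (50, 100), residuals (0.3, 0): sqrt((50/150)*0.09)
  expect_equal(wrmse(t2, p2, weight_scheme("linear_relative")),
               sqrt(50 / 150 * 0.09), tolerance = 1e-12)
  expect_equal(wrmse(t2, t2, weight_scheme("linear_relative")), 0)

  curves <- fixture_curves(6, seed = 9)
  sch <- weight_scheme("linear_relative")
  a <- curves[[1]]; b <- curves[[2]]; cc <- curves[[3]]
  # symmetry in the residuals (weights fixed by the first argument's grid/rx)
  expect_equal(wrmse(a, b, sch),
               {
                 w <- make_weight_vector(sch, a)
                 r <- b$volume_fraction - a$volume_fraction
                 sqrt(sum(w / sum(w) * r^2))
               })
  # triangle inequality on residual vectors: d(a,c) <= d(a,b)+d(b,c) with a
  # common weight vector
  w <- make_weight_vector(sch, a) ; w <- w / sum(w)
  dd <- function(x, y) sqrt(sum(w * (x$volume_fraction - y$volume_fraction)^2))
  expect_lte(dd(a, cc), dd(a, b) + dd(b, cc) + 1e-12)
  # constant scheme reduces to RMSE
  expect_equal(wrmse(a, b, weight_scheme("constant")),
               sqrt(mean((a$volume_fraction - b$volume_fraction)^2)),
               tolerance = 1e-12)
})
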