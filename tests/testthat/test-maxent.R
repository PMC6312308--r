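test_that("feature expansion produces the expected columns", {
  X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("PC", 1:4)))
  expect_equal(ncol(expand_features(X, "linear")), 4)
  expect_equal(ncol(expand_features(X, c("linear", "quadratic"))), 8)
  expect_equal(ncol(expand_features(X, c("linear", "quadratic", "product"))),
               4 + 4 + 6)
  expect_equal(expand_features(X, c("linear", "quadratic"))[, "PC2^2"],
               X[, "PC2"]^2)
})

test_that("background sampling is uniform, seeded, and region-restricted", {
  w <- default_world()
  bg <- sample_background(w$pc, NULL, 1000, seed = 3)
  expect_length(bg, 1000)
  expect_equal(anyDuplicated(bg), 0)
  expect_identical(bg, sample_background(w$pc, NULL, 1000, seed = 3))
  # single-row latitude band: all cells in that row
  band <- calibration_region(lat_max = 12.5, lat_min = 12.25)
  bgb <- sample_background(w$pc, band, 50, seed = 3)
  expect_true(all(((bgb - 1) %% w$grid$n_rows) + 1 == 1))
  # requesting more cells than the region holds returns all, with warning
  expect_warning(all_band <- sample_background(w$pc, band, 500, seed = 3),
                 "using all")
  expect_length(all_band, w$grid$n_cols)
  expect_error(sample_background(w$pc, calibration_region(-40, -50), 10, 1),
               "region error")
  # draws are uniform over the region (chi-square on row marginals)
  g <- tiny_grid(10, 10)
  st <- env_stack(list(a = matrix(rnorm(100), 10, 10)), g)
  draws <- unlist(lapply(1:100, function(s) sample_background(st, NULL, 90,
                                                              seed = s)))
  rows <- ((draws - 1) %% 10) + 1
  expect_gt(stats::chisq.test(tabulate(rows, 10))$p.value, 0.01)
})

test_that("heavy regularization shrinks every weight to exactly zero", {
  w <- default_world()
  pres <- with_seed(11, sample(w$bg, 100))
  m <- fit_maxent_cells(pres, w$bg, w$pc, beta = 1e6)
  expect_true(all(m$weights == 0))
  # flat model: suitability 1 at every valid in-range cell
  pr <- predict(m, w$pc)
  v <- pr$values[!is.na(pr$values) & !attr(pr, "novelty")]
  expect_true(all(v == 1))
})

test_that("fitted models satisfy the Gibbs normalization invariant", {
  w <- default_world()
  occ <- sample_occurrences(w$truth, 300, 0, 0, seed = 21)
  m <- fit_maxent(occ, w$bg, w$pc)
  Fb <- expand_features(stack_values_at(w$pc, w$bg), m$feature_spec$classes)
  Fb <- sweep(sweep(Fb, 2, m$feature_center, "-"), 2, m$feature_scale, "/")
  eta <- drop(Fb %*% m$weights)
  expect_equal(mean(exp(eta - m$log_normalizer)), 1, tolerance = 1e-6)
  expect_lt(m$kkt, 1e-6)
})

test_that("a no-signal fit is near-flat with penalty-scale weights", {
  w <- default_world()
  pres <- with_seed(77, sample(w$bg, 200))
  m <- fit_maxent_cells(pres, w$bg, w$pc)
  # under the null, activations stay at the mean-fluctuation scale 1/sqrt(m)
  expect_lte(max(abs(m$weights)), 2 / sqrt(200))
  pr <- predict(m, w$pc)
  v <- pr$values[!is.na(pr$values)]
  expect_lt(stats::sd(v) / mean(v), 0.15)
})

test_that("a top-decile PC1 presence sample yields a positive PC1 weight", {
  w <- default_world()
  pc1 <- w$pc$layers$PC1
  cand <- which(pc1 >= stats::quantile(pc1, 0.9, na.rm = TRUE))
  pres <- with_seed(13, sample(cand, 150))
  m <- fit_maxent_cells(pres, w$bg, w$pc, spec = maxent_features("linear"))
  expect_gt(m$weights[["PC1"]], 0)
})

test_that("the objective is convex: restarts agree", {
  w <- default_world()
  occ <- sample_occurrences(w$truth, 200, 0, 0, seed = 31)
  idx <- cell_index(w$grid, occ$longitude, occ$latitude)
  m0 <- fit_maxent_cells(idx, w$bg, w$pc)
  m1 <- fit_maxent_cells(idx, w$bg, w$pc,
                         init = with_seed(5, stats::rnorm(16, sd = 0.5)))
  Fb <- expand_features(stack_values_at(w$pc, w$bg), c("linear", "quadratic"))
  Fb <- sweep(sweep(Fb, 2, m0$feature_center, "-"), 2, m0$feature_scale, "/")
  Fp <- expand_features(stack_values_at(w$pc, idx), c("linear", "quadratic"))
  Fp <- sweep(sweep(Fp, 2, m0$feature_center, "-"), 2, m0$feature_scale, "/")
  obj <- function(m) gibbs_objective(m$weights, colMeans(Fp), Fb, m$penalty)
  expect_lt(abs(obj(m0) - obj(m1)), 1e-6)
  p0 <- predict(m0, w$pc)$values
  p1 <- predict(m1, w$pc)$values
  expect_lt(max(abs(p0 - p1), na.rm = TRUE), 1e-4)
})

test_that("prediction normalizes to 1 and zeroes novel environments", {
  w <- default_world()
  occ <- sample_occurrences(w$truth, 200, 0, 0, seed = 41)
  m <- fit_maxent(occ, w$bg, w$pc)
  pr <- predict(m, w$pc)
  expect_equal(max(pr$values, na.rm = TRUE), 1)
  expect_true(all(pr$values >= 0 & pr$values <= 1, na.rm = TRUE))
  # shift PC1 far beyond the training range: extrapolation must be off
  shifted <- w$pc$layers
  shifted$PC1 <- shifted$PC1 + 2 * diff(range(shifted$PC1, na.rm = TRUE))
  pr2 <- predict(m, env_stack(shifted, w$grid, "future"))
  expect_true(all(pr2$values == 0, na.rm = TRUE))
  expect_true(all(attr(pr2, "novelty")[!is.na(pr2$values)]))
  expect_error(predict(m, env_stack(shifted[1:3], w$grid)), "schema error")
})

test_that("replicate bookkeeping: medians and ranges behave as order statistics", {
  w <- default_world()
  occ <- sample_occurrences(w$truth, 150, 0, 0, seed = 51)
  thin <- thin_to_grid(deduplicate(filter_precision(occ)), w$env$stack)
  one <- fit_replicates(thin, w$pc, n_replicates = 1, seed = 6,
                        background = w$bg)
  expect_equal(one$median_map$values, one$replicates[[1]]$values)
  expect_true(all(one$range_map$values == 0, na.rm = TRUE))
  reps <- fit_replicates(thin, w$pc, n_replicates = 3, seed = 6,
                         background = w$bg)
  arr <- simplify2array(lapply(reps$replicates, function(r) r$values))
  lo <- apply(arr, c(1, 2), min); hi <- apply(arr, c(1, 2), max)
  expect_true(all(reps$median_map$values >= lo - 1e-12 &
                    reps$median_map$values <= hi + 1e-12, na.rm = TRUE))
  expect_equal(reps$range_map$values, hi - lo)
  expect_true(all(reps$range_map$values >= 0, na.rm = TRUE))
})

test_that("too few presences raise a data error", {
  w <- default_world()
  occ <- sample_occurrences(w$truth, 20, 0, 0, seed = 61)[1:5, ]
  occ <- new_occurrence_set(as.data.frame(occ), "thinned")
  expect_error(fit_maxent(occ, w$bg, w$pc), "data error")
})
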