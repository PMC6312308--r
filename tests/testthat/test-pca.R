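test_that("layer exclusion drops the artifact-prone variables", {
  g <- tiny_grid(6, 6)
  layers <- lapply(1:19, function(i) matrix(rnorm(36), 6, 6))
  names(layers) <- paste0("bio", 1:19)
  stack <- env_stack(layers, g)
  out <- exclude_layers(stack)  # default set: bio8, bio9, bio18, bio19
  expect_equal(length(out$layers), 15)
  expect_false(any(c("bio8", "bio9", "bio18", "bio19") %in% stack_names(out)))
  expect_equal(stack_names(exclude_layers(stack, character(0))),
               stack_names(stack))
  expect_error(exclude_layers(stack, "bio99"), "bio99")
  expect_error(exclude_layers(stack, paste0("bio", 1:19)), "all layers")
})

test_that("two perfectly correlated layers give a rank-1 decomposition", {
  g <- tiny_grid(10, 10)
  a <- matrix(rnorm(100), 10, 10)
  stack <- env_stack(list(x = a, y = 3 * a - 1), g)
  pca <- fit_pca(stack)
  expect_equal(pca$variance_fraction, c(1, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCA transform satisfies its algebraic invariants", {
  w <- default_world()
  pca <- w$pca
  L <- pca$loadings
  # orthonormal loadings, normalized non-increasing variance fractions
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-10)
  expect_true(all(diff(pca$variance_fraction) <= 1e-12))
  expect_true(all(pca$sds > 0))
  # sign convention: largest-|loading| entry of each column is positive
  for (j in seq_len(ncol(L))) expect_gt(L[which.max(abs(L[, j])), j], 0)
  # self-projection: PC means 0, variances equal to the eigenvalues
  pc_all <- transform_stack(w$env$stack, pca, length(pca$eigenvalues))
  scores <- sapply(pc_all$layers, as.vector)
  expect_equal(unname(colMeans(scores)), rep(0, ncol(scores)),
               tolerance = 1e-8)
  expect_equal(unname(apply(scores, 2, var)), unname(pca$eigenvalues),
               tolerance = 1e-8)
  # reconstruction from all components recovers the input stack
  Z <- scores %*% t(L)
  X <- sweep(sweep(Z, 2, pca$sds, "*"), 2, pca$means, "+")
  orig <- sapply(w$env$stack$layers, as.vector)
  expect_equal(unname(X), unname(orig), tolerance = 1e-6)
})

test_that("a stack mixed from two latent fields concentrates in two components", {
  g <- raster_grid(60, 70, 0, 30, 0.5)
  e <- make_environment(g, n_latent = 2, n_layers = 15, seed = 4,
                        noise_sd = 1e-4)
  pca <- fit_pca(e$stack)
  expect_gt(sum(pca$variance_fraction[1:2]), 0.99)
})

test_that("future stacks are projected with present-day statistics only", {
  w <- default_world()
  pca <- w$pca
  fut_layers <- lapply(w$env$stack$layers, function(m) m * 2 + 1)
  fut <- env_stack(fut_layers, w$grid, scenario_tag = "future")
  out <- transform_stack(fut, pca, 3)
  # manual projection with the present-day means/sds must agree exactly
  X <- sapply(fut$layers, as.vector)[, pca$layer_names]
  Z <- sweep(sweep(X, 2, pca$means, "-"), 2, pca$sds, "/")
  P <- Z %*% pca$loadings[, 1:3]
  expect_equal(unname(sapply(out$layers, as.vector)), unname(P),
               tolerance = 1e-12)
  # a future stack identical to the present maps to the identical PC stack
  same <- transform_stack(w$env$stack, pca, 8)
  expect_equal(same$layers, w$pc$layers)
  expect_error(transform_stack(env_stack(list(zz = w$env$stack$layers[[1]]),
                                         w$grid), pca),
               "schema error")
})

test_that("component selection follows the cumulative-variance rule", {
  fake <- structure(list(variance_fraction =
                           c(0.7, 0.2, 0.09, 0.009, 0.0009, 0.0001)),
                    class = "pca_transform")
  # cumulative sum reaches 0.9999 exactly at k = 5
  expect_equal(select_components(fake, 0.9999), 5L)
  expect_equal(select_components(fake, 0.5), 1L)
  expect_equal(select_components(fake, 1.0), 6L)
  fake2 <- structure(list(variance_fraction = c(0.7, 0.3)),
                     class = "pca_transform")
  expect_equal(select_components(fake2, 0.5), 1L)
  expect_error(select_components(fake, 0), "variance_target")
})

test_that("degenerate stacks are rejected with informative errors", {
  g <- tiny_grid(5, 5)
  const <- env_stack(list(a = matrix(1, 5, 5), b = matrix(rnorm(25), 5, 5)), g)
  expect_error(fit_pca(const), "constant layer.*a")
  one <- env_stack(list(a = matrix(rnorm(25), 5, 5)), g)
  expect_error(fit_pca(one), "at least 2")
})
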