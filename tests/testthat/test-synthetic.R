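test_that("environment generation is deterministic and respects the mask", {
  g <- tiny_grid(20, 25, res = 0.5)
  e1 <- make_environment(g, n_latent = 2, n_layers = 6, seed = 9)
  e2 <- make_environment(g, n_latent = 2, n_layers = 6, seed = 9)
  expect_identical(e1$stack$layers, e2$stack$layers)
  expect_identical(e1$latent, e2$latent)
  e3 <- make_environment(g, n_latent = 2, n_layers = 6, seed = 10)
  expect_false(identical(e1$stack$layers, e3$stack$layers))
  # no nodata outside the supplied mask
  mask <- matrix(TRUE, 20, 25); mask[1:5, 1:5] <- FALSE
  em <- make_environment(g, n_latent = 2, n_layers = 4, seed = 9, mask = mask)
  for (l in em$stack$layers) expect_identical(unname(is.na(l)), unname(!mask))
  expect_error(make_environment(g, n_latent = 0, n_layers = 4), "n_latent")
})

test_that("layers mixed from two latent fields have near-rank-2 correlation", {
  g <- raster_grid(60, 70, 0, 30, 0.5)
  e <- make_environment(g, n_latent = 2, n_layers = 15, seed = 4,
                        noise_sd = 1e-4)
  X <- sapply(e$stack$layers, as.vector)
  ev <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[3], 0.01 * ev[1])
})

test_that("true suitability follows the Gaussian niche formula", {
  g <- tiny_grid(5, 5)
  latent <- list(matrix(seq(-2, 2, length.out = 25), 5, 5),
                 matrix(0, 5, 5))
  n <- true_niche(center = c(latent[[1]][3, 3], 0), widths = c(1, 1))
  s <- make_species(latent, n, g)
  expect_equal(s$values[3, 3], 1)                 # truth = 1 at the center
  expect_true(all(s$values <= 1 & s$values >= 0))
  # widths -> infinity gives a constant map at max_suitability
  wide <- make_species(latent, true_niche(c(0, 0), c(1e9, 1e9), 0.8), g)
  expect_equal(max(abs(wide$values - 0.8)), 0, tolerance = 1e-12)
  # doubling widths never decreases suitability anywhere
  s2 <- make_species(latent, true_niche(n$center, 2 * n$widths), g)
  expect_true(all(s2$values >= s$values))
  expect_error(make_species(latent, true_niche(c(0, 0, 0), c(1, 1, 1)), g),
               "dimension")
})

test_that("occurrence sampling tracks suitability and its contaminants", {
  g <- tiny_grid(10, 10)
  v <- matrix(0, 10, 10)
  v[1, 1] <- 1
  one <- sample_occurrences(env_layer(v, g), 50, 0, 0, seed = 2)
  rc <- cell_of(g, one$longitude, one$latitude)
  expect_true(all(rc$row == 1 & rc$col == 1))  # single suitable cell
  # clean sample: all unique, all exact
  w <- default_world()
  clean <- sample_occurrences(w$truth, 200, 0, 0, seed = 3)
  expect_equal(nrow(clean), 200)
  expect_true(all(clean$precision_flag == "exact"))
  expect_equal(anyDuplicated(clean[, c("longitude", "latitude")]), 0)
  # contaminated sample: bookkeeping matches requested rates
  dirty <- sample_occurrences(w$truth, 400, dup_rate = 0.3,
                              lowprec_rate = 0.25, seed = 4)
  expect_equal(nrow(dirty), 520)
  expect_equal(attr(dirty, "gen_n_dup"), 120)
  expect_gte(attr(dirty, "gen_n_low"), 100)  # 100 base + low-flagged copies
  expect_error(sample_occurrences(env_layer(matrix(0, 10, 10), g), 10, 0, 0),
               "sampling error")
})

test_that("sampled cell frequencies match true suitability (chi-square)", {
  g <- tiny_grid(10, 1)
  p <- c(0.30, 0.05, 0.15, 0.02, 0.10, 0.08, 0.04, 0.06, 0.12, 0.08)
  truth <- env_layer(matrix(p, 10, 1), g)
  occ <- sample_occurrences(truth, 5000, 0, 0, seed = 8)
  rows <- cell_of(g, occ$longitude, occ$latitude)$row
  obs <- tabulate(rows, nbins = 10)
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.01)
})

test_that("future stacks shift monotonically with scenario intensity", {
  g <- tiny_grid(15, 18)
  e <- make_environment(g, n_latent = 2, n_layers = 5, seed = 6)
  spec <- scenario_spec(n_gcms = 3,
                        rcp_shifts = c(rcp26 = 0.25, rcp45 = 0.5,
                                       rcp60 = 0.75, rcp85 = 1.25),
                        periods = c(`2050` = 1, `2070` = 1.5))
  fut <- make_future(e, spec, seed = 12, pert_sd = 0.1)
  expect_length(fut, 3 * 4 * 2)
  # zero shift and zero perturbation reproduce the present stack exactly
  null_spec <- scenario_spec(n_gcms = 2, rcp_shifts = c(a = 0, b = 1),
                             periods = c(p = 1))
  fut0 <- make_future(e, null_spec, seed = 12, pert_sd = 0)
  expect_equal(fut0[["gcm1_a_p"]]$layers, e$stack$layers, tolerance = 1e-14)
  # per-cell |future - present| of a layer increases across RCPs
  d <- vapply(c("rcp26", "rcp45", "rcp60", "rcp85"), function(r)
    mean(abs(fut[[sprintf("gcm1_%s_2050", r)]]$layers$env01 -
               e$stack$layers$env01)), numeric(1))
  expect_true(all(diff(d) > 0))
  # 2070 shifts exceed 2050 shifts at equal RCP
  d70 <- mean(abs(fut[["gcm1_rcp45_2070"]]$layers$env01 - e$stack$layers$env01))
  expect_gt(d70, d["rcp45"])
})

test_that("scenario specifications are validated", {
  expect_error(scenario_spec(n_gcms = 1), "n_gcms")
  expect_error(scenario_spec(rcp_shifts = c(a = 0.5, b = 0.25)), "increase")
  expect_equal(scenario_spec()$n_gcms, 9L)
  expect_length(scenario_spec()$rcp_shifts, 4)
  expect_length(scenario_spec()$periods, 2)
})

test_that("monotone shift of zero-shift GCM equals perturbation only", {
  # determinism of sub-seeded GCM perturbations
  g <- tiny_grid(12, 12)
  e <- make_environment(g, n_latent = 2, n_layers = 4, seed = 3)
  s <- scenario_spec(n_gcms = 2, rcp_shifts = c(lo = 0.2, hi = 0.8),
                     periods = c(p = 1))
  f1 <- make_future(e, s, seed = 5)
  f2 <- make_future(e, s, seed = 5)
  expect_identical(f1, f2)
  expect_false(identical(f1[["gcm1_lo_p"]]$layers, f1[["gcm2_lo_p"]]$layers))
})
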