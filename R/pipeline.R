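#' Default configuration of the synthetic-world pipeline
#'
#' The desk-scale virtual world: a 100 x 120 geographic grid at 0.25 degrees,
#' 15 climate-like layers mixed from 2 latent gradients, two species with
#' overlapping Gaussian niches, 400 base presences each (contaminated with
#' duplicates and low-precision coordinates), and 9 pseudo-GCMs x 4 RCPs x 2
#' periods = 72 future stacks.
#'
#' @return A named list of parameters accepted by [run_pipeline()].
#' @export
pipeline_config <- function() {
  list(
    grid = raster_grid(100, 120, x_min = 0, y_max = 12.5, resolution = 0.25),
    n_latent = 2, n_layers = 15, smooth_sigma = 6, noise_sd = 0.05,
    species = list(
      aegypti_like = true_niche(center = c(0.5, 0.3), widths = c(1, 1)),
      albopictus_like = true_niche(center = c(-0.2, 0.6), widths = c(1, 1))
    ),
    n_occurrences = 400, dup_rate = 0.3, lowprec_rate = 0.25,
    n_independent = 200,
    scenario = scenario_spec(), pert_sd = 0.15,
    n_components = 8, feature_classes = c("linear", "quadratic"),
    beta = 1, background_n = 10000, n_replicates = 10,
    train_fraction = 0.5, split_fraction = 0.5, E = 0.05,
    proc_iterations = 500, overlap_replicates = 100,
    write_rasters = TRUE
  )
}

#' Run the full niche-modeling pipeline on a synthetic world
#'
#' Generates the virtual world, runs the occurrence-cleaning cascade, fits the
#' present-day PCA and projects every scenario stack through it, fits
#' bootstrapped maximum-entropy replicates per species, thresholds at the
#' allowed omission rate, evaluates with partial ROC and the cumulative
#' binomial test, builds per-RCP ensemble medians, uncertainty ranges,
#' stability maps and area-change tables, and runs the background-similarity
#' test in both directions. All outputs (occurrence CSVs, ASCII rasters, and a
#' JSON manifest with every parameter, seed, count, threshold and statistic)
#' are written under `outdir` and are bit-reproducible from `(config, seed)`.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master integer seed; every stage derives its own sub-seed from
#'   it deterministically.
#' @param config Parameter list as from [pipeline_config()]; supplied entries
#'   override the defaults.
#' @return Invisibly, a list with the per-species results, the ensemble
#'   products, the overlap tests, and the manifest.
#' @export
run_pipeline <- function(outdir, seed = 1, config = list()) {
  cfg <- utils::modifyList(pipeline_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  grid <- cfg$grid

  env <- make_environment(grid, n_latent = cfg$n_latent,
                          n_layers = cfg$n_layers, seed = sub_seed(seed, 10),
                          smooth_sigma = cfg$smooth_sigma,
                          noise_sd = cfg$noise_sd)
  futures <- make_future(env, cfg$scenario, seed = sub_seed(seed, 11),
                         pert_sd = cfg$pert_sd)

  pca <- fit_pca(env$stack)
  k <- min(cfg$n_components, length(pca$variance_fraction))
  pc_present <- transform_stack(env$stack, pca, k)
  spec_feats <- maxent_features(cfg$feature_classes)
  background <- sample_background(pc_present, m = NULL, n = cfg$background_n,
                                  seed = sub_seed(seed, 12))

  species_results <- list()
  rcps <- names(cfg$scenario$rcp_shifts)
  periods <- names(cfg$scenario$periods)

  for (si in seq_along(cfg$species)) {
    sp <- names(cfg$species)[si]
    truth <- make_species(env$latent, cfg$species[[sp]], grid)
    raw <- sample_occurrences(truth, cfg$n_occurrences, cfg$dup_rate,
                              cfg$lowprec_rate, seed = sub_seed(seed, 20, si),
                              species = sp)
    independent <- sample_occurrences(truth, cfg$n_independent, 0, 0,
                                      seed = sub_seed(seed, 21, si),
                                      species = sp)
    thinned <- thin_to_grid(deduplicate(filter_precision(raw)), env$stack)
    halves <- split_calibration(thinned, cfg$split_fraction,
                                seed = sub_seed(seed, 22, si))

    reps <- fit_replicates(halves$calibration, pc_present,
                           n_replicates = cfg$n_replicates,
                           train_fraction = cfg$train_fraction,
                           seed = sub_seed(seed, 23, si),
                           background = background, spec = spec_feats,
                           beta = cfg$beta)
    thr <- threshold_E(reps$median_map, halves$calibration, cfg$E)
    proc <- partial_roc(reps$median_map, halves$evaluation, E = cfg$E,
                        n_iterations = cfg$proc_iterations,
                        seed = sub_seed(seed, 24, si))
    binom <- binomial_test(thr$binary, independent)

    ensembles <- list()
    area_table <- list()
    for (rcp in rcps) {
      for (per in periods) {
        gcm_medians <- vector("list", cfg$scenario$n_gcms)
        for (g in seq_len(cfg$scenario$n_gcms)) {
          tag <- sprintf("gcm%d_%s_%s", g, rcp, per)
          pc_fut <- transform_stack(futures[[tag]], pca, k)
          preds <- lapply(reps$models, function(m) predict(m, pc_fut)$values)
          arr <- array(unlist(preds),
                       dim = c(grid$n_rows, grid$n_cols, length(preds)))
          gcm_medians[[g]] <- env_layer(apply(arr, c(1, 2), stats::median),
                                        grid, tag)
        }
        ens <- ensemble_future(gcm_medians, thr$threshold$tau, rcp, per)
        gcm_bin <- lapply(gcm_medians, function(m) {
          b <- m$values
          b[!is.na(b)] <- as.numeric(b[!is.na(b)] >= thr$threshold$tau)
          env_layer(b, grid, paste0(m$name, "_binary"))
        })
        stab <- stability_map(thr$binary, gcm_bin, ens$binary)
        chg <- area_change(thr$binary, ens$binary)
        key <- paste(rcp, per, sep = "_")
        ensembles[[key]] <- list(ensemble = ens, stability = stab,
                                 area_change = chg)
        area_table[[key]] <- chg
      }
    }

    sp_dir <- file.path(outdir, sp)
    dir.create(sp_dir, showWarnings = FALSE)
    write_occurrences(thinned, file.path(sp_dir, "occurrences_thinned.csv"))
    write_occurrences(halves$calibration,
                      file.path(sp_dir, "occurrences_calibration.csv"))
    write_occurrences(halves$evaluation,
                      file.path(sp_dir, "occurrences_evaluation.csv"))
    if (isTRUE(cfg$write_rasters)) {
      write_raster(truth, file.path(sp_dir, "true_suitability.asc"))
      write_raster(reps$median_map, file.path(sp_dir, "median_present.asc"))
      write_raster(reps$range_map, file.path(sp_dir, "uncertainty_present.asc"))
      write_raster(thr$binary, file.path(sp_dir, "binary_present.asc"))
      for (key in names(ensembles)) {
        write_raster(ensembles[[key]]$ensemble$ensemble_median,
                     file.path(sp_dir, sprintf("ensemble_median_%s.asc", key)))
        write_raster(ensembles[[key]]$ensemble$uncertainty_range,
                     file.path(sp_dir, sprintf("uncertainty_%s.asc", key)))
        write_raster(ensembles[[key]]$stability,
                     file.path(sp_dir, sprintf("stability_%s.asc", key)))
      }
    }

    species_results[[sp]] <- list(
      truth = truth, raw = raw, thinned = thinned, halves = halves,
      replicates = reps, threshold = thr$threshold, binary = thr$binary,
      proc = proc, binomial = binom, ensembles = ensembles,
      area_table = area_table, counts_log = counts_log(thinned))
  }

  sp1 <- species_results[[1]]; sp2 <- species_results[[2]]
  overlap_ab <- background_similarity_test(
    sp1$replicates$median_map, sp2$replicates$median_map, m_b = NULL,
    n_points_b = nrow(sp2$thinned), pc_stack = pc_present,
    background = background, n_replicates = cfg$overlap_replicates,
    seed = sub_seed(seed, 30), spec = spec_feats, beta = cfg$beta)
  overlap_ba <- background_similarity_test(
    sp2$replicates$median_map, sp1$replicates$median_map, m_b = NULL,
    n_points_b = nrow(sp1$thinned), pc_stack = pc_present,
    background = background, n_replicates = cfg$overlap_replicates,
    seed = sub_seed(seed, 31), spec = spec_feats, beta = cfg$beta)

  manifest <- list(
    seed = seed,
    grid = cfg$grid[c("n_rows", "n_cols", "x_min", "y_max", "resolution")],
    parameters = cfg[c("n_latent", "n_layers", "smooth_sigma", "noise_sd",
                       "n_occurrences", "dup_rate", "lowprec_rate",
                       "n_independent", "pert_sd", "n_components",
                       "feature_classes", "beta", "background_n",
                       "n_replicates", "train_fraction", "split_fraction",
                       "E", "proc_iterations", "overlap_replicates")],
    scenario = list(n_gcms = cfg$scenario$n_gcms,
                    rcp_shifts = as.list(cfg$scenario$rcp_shifts),
                    periods = as.list(cfg$scenario$periods)),
    pca_variance_fraction = pca$variance_fraction,
    n_components_used = k,
    species = lapply(species_results, function(r) list(
      counts_log = as.list(r$counts_log),
      threshold = r$threshold,
      proc = r$proc[c("n_iterations", "min", "max", "mean", "median",
                      "n_ns", "p_value")],
      binomial = r$binomial[c("n", "s", "p", "p_value")],
      area_change = r$area_table
    )),
    overlap = list(
      a_vs_background_b = overlap_ab[c("D_observed", "I_observed",
                                       "percentile_5_D", "percentile_5_I",
                                       "reject_D", "reject_I", "n_replicates")],
      b_vs_background_a = overlap_ba[c("D_observed", "I_observed",
                                       "percentile_5_D", "percentile_5_I",
                                       "reject_D", "reject_I", "n_replicates")]
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(env = env, pca = pca, species = species_results,
                 overlap = list(a_vs_b = overlap_ab, b_vs_a = overlap_ba),
                 manifest = manifest))
}
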