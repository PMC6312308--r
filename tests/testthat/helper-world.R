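# Shared fixtures, built in code and cached for the session.

.world_cache <- new.env(parent = emptyenv())

# the default desk-scale virtual world: 100 x 120 grid, 15 layers from 2
# latent gradients, Gaussian-niche species, 8 PCs, 10k background cells
default_world <- function() {
  if (is.null(.world_cache$w)) {
    g <- raster_grid(100, 120, x_min = 0, y_max = 12.5, resolution = 0.25)
    env <- make_environment(g, n_latent = 2, n_layers = 15, seed = 42)
    truth <- make_species(env$latent, true_niche(c(0.5, 0.3), c(1, 1)), g)
    pca <- fit_pca(env$stack)
    pc <- transform_stack(env$stack, pca, 8)
    bg <- sample_background(pc, NULL, 10000, seed = 5)
    .world_cache$w <- list(grid = g, env = env, truth = truth,
                           pca = pca, pc = pc, bg = bg)
  }
  .world_cache$w
}

tiny_grid <- function(nr = 10, nc = 10, res = 1) {
  raster_grid(nr, nc, x_min = 0, y_max = nr * res, resolution = res)
}

# hand-build an occurrence set at a given stage
occ_set <- function(lon, lat, species = "sp", flag = "exact", stage = "raw") {
  df <- data.frame(species = rep_len(species, length(lon)),
                   longitude = lon, latitude = lat,
                   precision_flag = rep_len(flag, length(lon)),
                   source_id = sprintf("t%04d", seq_along(lon)),
                   stringsAsFactors = FALSE)
  new_occurrence_set(df, stage)
}

# single-layer helper
layer_of <- function(values, grid, name = "x") env_layer(values, grid, name)
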