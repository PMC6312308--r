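#' Specify a species' true environmental niche
#'
#' Ground truth for the virtual world: suitability is an axis-aligned Gaussian
#' in latent-environment space,
#' `max_suitability * exp(-0.5 * sum(((x - center) / widths)^2))`, always in
#' `[0, 1]`. Smooth and unimodal, so it is recoverable by a maximum-entropy
#' model with quadratic features.
#'
#' @param center Numeric vector: niche optimum in latent space.
#' @param widths Positive vector, one Gaussian scale per latent axis.
#' @param max_suitability Peak suitability in `(0, 1]`.
#' @return Object of class `true_niche`.
#' @export
true_niche <- function(center, widths, max_suitability = 1) {
  if (length(center) != length(widths)) stop("center and widths lengths differ")
  if (any(widths <= 0)) stop("widths must be positive")
  if (max_suitability <= 0 || max_suitability > 1)
    stop("max_suitability must be in (0, 1]")
  structure(list(center = center, widths = widths,
                 max_suitability = max_suitability), class = "true_niche")
}

#' Specify the future-scenario design
#'
#' @param n_gcms Number of pseudo general circulation models (default 9).
#' @param rcp_shifts Named vector mapping RCP label to the magnitude of the
#'   shared directional shift in latent space; must strictly increase with
#'   scenario intensity. Units are standard deviations of the (standardized)
#'   latent fields.
#' @param periods Named vector of period multipliers applied to the shift
#'   (later periods larger).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_gcms = 9,
                          rcp_shifts = c(rcp26 = 0.25, rcp45 = 0.5,
                                         rcp60 = 0.75, rcp85 = 1.25),
                          periods = c(`2050` = 1, `2070` = 1.5)) {
  if (n_gcms < 2) stop("n_gcms must be at least 2")
  if (any(diff(rcp_shifts) <= 0))
    stop("rcp_shifts must strictly increase with RCP intensity")
  if (is.null(names(rcp_shifts)) || is.null(names(periods)))
    stop("rcp_shifts and periods must be named")
  structure(list(n_gcms = as.integer(n_gcms), rcp_shifts = rcp_shifts,
                 periods = periods), class = "scenario_spec")
}

# separable Gaussian blur with edge renormalization (kernel truncated at 3*sigma)
smooth_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  band <- function(n) {
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - half):min(n, i + half)
      w <- k[j - i + half + 1]
      K[i, j] <- w / sum(w)
    }
    K
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

standardize_field <- function(m, mask = NULL) {
  v <- if (is.null(mask)) m else m[mask]
  (m - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
}

#' Generate a correlated, spatially autocorrelated environmental stack
#'
#' Emulates the statistical structure of a bioclimatic layer set: a small
#' number of smooth latent gradients (white noise convolved with a Gaussian
#' kernel, then standardized) are mixed into many mutually correlated observed
#' layers with a fixed random linear mixing matrix plus small independent
#' noise, so the stack has low effective rank and PCA is meaningful.
#'
#' @param grid A [raster_grid()].
#' @param n_latent Number of latent gradients (default 2).
#' @param n_layers Number of observed layers (default 15, the count retained
#'   after excluding the artifact-prone bioclim variables).
#' @param seed Integer seed; the same `(grid, seed)` reproduces the stack
#'   bit-for-bit.
#' @param smooth_sigma Gaussian kernel scale in cells (spatial autocorrelation
#'   range).
#' @param noise_sd Standard deviation of per-layer independent noise.
#' @param mask Optional logical matrix; cells where `mask` is `FALSE` become
#'   nodata (e.g. an ocean mask).
#' @return Object of class `synthetic_environment`: a list with the `stack`
#'   ([env_stack()]), the `latent` fields (list of matrices, the ground
#'   truth), the `mixing` matrix, and the stored per-layer `noise`
#'   realizations (reused when building future stacks).
#' @export
make_environment <- function(grid, n_latent = 2, n_layers = 15, seed = 1,
                             smooth_sigma = 6, noise_sd = 0.05, mask = NULL) {
  if (n_latent < 1) stop("n_latent must be at least 1")
  if (n_latent > n_layers) stop("n_latent must not exceed n_layers")
  nr <- grid$n_rows; nc <- grid$n_cols
  with_seed(seed, {
    latent <- lapply(seq_len(n_latent), function(k)
      standardize_field(smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                                      smooth_sigma), mask))
    mixing <- matrix(stats::rnorm(n_layers * n_latent), n_layers, n_latent)
    noise <- lapply(seq_len(n_layers), function(i)
      matrix(stats::rnorm(nr * nc), nr, nc))
  })
  layers <- mix_layers(latent, mixing, noise, noise_sd, mask)
  structure(list(
    stack = env_stack(layers, grid, scenario_tag = "present"),
    latent = latent, mixing = mixing, noise = noise,
    noise_sd = noise_sd, smooth_sigma = smooth_sigma, mask = mask,
    grid = grid, seed = seed
  ), class = "synthetic_environment")
}

mix_layers <- function(latent, mixing, noise, noise_sd, mask) {
  n_layers <- nrow(mixing)
  layers <- lapply(seq_len(n_layers), function(i) {
    m <- Reduce(`+`, Map(function(l, w) w * l, latent, mixing[i, ]))
    m <- m + noise_sd * noise[[i]]
    if (!is.null(mask)) m[!mask] <- NA
    m
  })
  names(layers) <- sprintf("env%02d", seq_len(n_layers))
  layers
}

#' Evaluate a species' true suitability on the latent fields
#'
#' @param latent List of latent-field matrices (from [make_environment()]).
#' @param niche A [true_niche()] of matching dimension.
#' @param grid The [raster_grid()] of the fields.
#' @return An [env_layer()] of true suitability in `[0, 1]`.
#' @export
make_species <- function(latent, niche, grid) {
  if (length(latent) != length(niche$center))
    stop("niche dimension (", length(niche$center),
         ") does not match number of latent fields (", length(latent), ")")
  q <- Reduce(`+`, Map(function(l, c, w) ((l - c) / w)^2,
                       latent, as.list(niche$center), as.list(niche$widths)))
  env_layer(niche$max_suitability * exp(-0.5 * q), grid, name = "truth")
}

#' Sample contaminated occurrence records from a true suitability map
#'
#' Base records are drawn cell-by-cell with probability proportional to true
#' suitability and placed uniformly within their cell (a probability-of-
#' occurrence interpretation matching the presence-background estimand). The
#' sample is then contaminated the way real compilations are: a fraction
#' `dup_rate` of records is duplicated exactly, and a fraction `lowprec_rate`
#' is rounded to one decimal place and flagged low-precision. These
#' contaminants are what the occurrence-preparation cascade must remove.
#'
#' @param truth An [env_layer()] of true suitability.
#' @param n Number of base records.
#' @param dup_rate Fraction of base records duplicated exactly.
#' @param lowprec_rate Fraction of base records degraded to 1-decimal
#'   coordinates.
#' @param seed Integer seed.
#' @param species Species label.
#' @return An occurrence set at stage `"raw"`, with attributes `gen_n_low` and
#'   `gen_n_dup` recording the generator's own contamination bookkeeping.
#' @export
sample_occurrences <- function(truth, n, dup_rate = 0.3, lowprec_rate = 0.25,
                               seed = 1, species = "species") {
  g <- truth$grid
  p <- as.vector(truth$values)
  p[is.na(p)] <- 0
  if (all(p <= 0)) stop("sampling error: truth map has no positive suitability")
  with_seed(seed, {
    idx <- sample.int(length(p), n, replace = TRUE, prob = p)
    row <- ((idx - 1L) %% g$n_rows) + 1L
    col <- ((idx - 1L) %/% g$n_rows) + 1L
    lon <- g$x_min + (col - 1L + stats::runif(n)) * g$resolution
    lat <- g$y_max - (row - 1L + stats::runif(n)) * g$resolution
    flag <- rep("exact", n)
    n_low <- round(lowprec_rate * n)
    if (n_low > 0) {
      low_i <- sample.int(n, n_low)
      lon[low_i] <- round(lon[low_i], 1)
      lat[low_i] <- round(lat[low_i], 1)
      flag[low_i] <- "low"
    }
    df <- data.frame(species = species, longitude = lon, latitude = lat,
                     precision_flag = flag,
                     source_id = sprintf("occ%05d", seq_len(n)),
                     stringsAsFactors = FALSE)
    n_dup <- round(dup_rate * n)
    if (n_dup > 0) {
      dup_i <- sample.int(n, n_dup, replace = n_dup > n)
      dups <- df[dup_i, ]
      dups$source_id <- sprintf("dup%05d", seq_len(n_dup))
      df <- rbind(df, dups)
    }
  })
  occ <- new_occurrence_set(df, "raw")
  attr(occ, "gen_n_low") <- sum(df$precision_flag == "low")
  attr(occ, "gen_n_dup") <- nrow(df) - n
  occ
}

# deterministic sub-seed derivation, kept below 2^31
sub_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.double(seed %% 2147483647)
  for (p in parts) s <- (s * 69069 + p * 7919 + 1) %% 2147483647
  as.integer(s)
}

#' Generate pseudo-GCM future environmental stacks
#'
#' For every `(gcm, rcp, period)` combination the latent fields receive a
#' shared directional shift of magnitude `rcp_shift * period_multiplier` along
#' a fixed unit vector in latent space, plus a GCM-specific smooth
#' perturbation field (distinct deterministic sub-seed per GCM). Layers are
#' then mixed with the same mixing matrix and noise realization as the present
#' stack, so a zero shift with zero perturbation reproduces the present stack
#' exactly.
#'
#' @param env A `synthetic_environment` from [make_environment()].
#' @param spec A [scenario_spec()].
#' @param seed Integer seed (GCM sub-seeds derive from it deterministically).
#' @param pert_sd Amplitude of GCM-specific perturbations (latent sd units).
#' @return Named list of [env_stack()]s, one per combination, named
#'   `gcm<g>_<rcp>_<period>`; each carries its `scenario_tag`.
#' @export
make_future <- function(env, spec = scenario_spec(), seed = 1, pert_sd = 0.15) {
  n_latent <- length(env$latent)
  u <- with_seed(sub_seed(seed, 1), {
    v <- stats::rnorm(n_latent)
    v / sqrt(sum(v^2))
  })
  nr <- env$grid$n_rows; nc <- env$grid$n_cols
  perts <- lapply(seq_len(spec$n_gcms), function(g) {
    if (pert_sd == 0) return(NULL)
    with_seed(sub_seed(seed, 2, g), lapply(seq_len(n_latent), function(k)
      standardize_field(smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                                      env$smooth_sigma), env$mask)))
  })
  out <- list()
  for (ri in seq_along(spec$rcp_shifts)) {
    for (pi in seq_along(spec$periods)) {
      mag <- spec$rcp_shifts[[ri]] * spec$periods[[pi]]
      for (g in seq_len(spec$n_gcms)) {
        shifted <- lapply(seq_len(n_latent), function(k) {
          l <- env$latent[[k]] + mag * u[k]
          if (!is.null(perts[[g]])) l <- l + pert_sd * perts[[g]][[k]]
          l
        })
        tag <- sprintf("gcm%d_%s_%s", g, names(spec$rcp_shifts)[ri],
                       names(spec$periods)[pi])
        out[[tag]] <- env_stack(
          mix_layers(shifted, env$mixing, env$noise, env$noise_sd, env$mask),
          env$grid,
          scenario_tag = list(gcm = g, rcp = names(spec$rcp_shifts)[ri],
                              period = names(spec$periods)[pi]))
      }
    }
  }
  out
}
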