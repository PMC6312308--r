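#' Normalize a suitability map to a probability surface
#'
#' Divides the (nonnegative) suitability values over the region's cells by
#' their sum, so they sum to one; cells outside the region (or nodata) are
#' `NA`. Idempotent on an already-normalized surface.
#'
#' @param map An [env_layer()] of suitability.
#' @param mask Optional logical matrix restricting the region (default: all
#'   non-nodata cells of the map).
#' @return A matrix summing to 1 over its non-`NA` cells.
#' @export
normalize_surface <- function(map, mask = NULL) {
  v <- if (inherits(map, "env_layer")) map$values else map
  if (is.null(mask)) mask <- !is.na(v)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  vals <- v[mask]
  if (any(is.na(vals))) stop("region includes nodata cells")
  if (any(vals < 0)) stop("suitability must be nonnegative")
  total <- sum(vals)
  if (total <= 0) stop("normalization error: surface is all zero on the region")
  out[mask] <- vals / total
  out
}

check_surfaces <- function(p1, p2) {
  if (!identical(dim(p1), dim(p2)) ||
      !identical(unname(is.na(p1)), unname(is.na(p2))))
    stop("schema error: probability surfaces on different masks")
}

#' Schoener's D niche-overlap statistic
#'
#' `D = 1 - 0.5 * sum(|p1 - p2|)` over the shared mask: 1 for identical
#' surfaces, 0 for disjoint supports.
#'
#' @param p1,p2 Probability surfaces from [normalize_surface()] on one mask.
#' @return D in `[0, 1]`.
#' @export
schoener_D <- function(p1, p2) {
  check_surfaces(p1, p2)
  max(0, min(1, 1 - 0.5 * sum(abs(p1 - p2), na.rm = TRUE)))
}

#' Hellinger-derived I niche-overlap statistic
#'
#' `I = 1 - 0.5 * sum((sqrt(p1) - sqrt(p2))^2)`, algebraically the
#' Bhattacharyya coefficient `sum(sqrt(p1 * p2))`: 1 for identical surfaces, 0
#' for disjoint supports. Always at least as large as Schoener's D.
#'
#' @param p1,p2 Probability surfaces from [normalize_surface()] on one mask.
#' @return I in `[0, 1]`.
#' @export
hellinger_I <- function(p1, p2) {
  check_surfaces(p1, p2)
  max(0, min(1, 1 - 0.5 * sum((sqrt(p1) - sqrt(p2))^2, na.rm = TRUE)))
}

#' Background similarity randomization test
#'
#' Asks whether the niche model of species A is more similar to that of
#' species B than to models built from random points drawn from B's
#' accessible area. Per replicate, `n_points_b` cells are drawn uniformly from
#' the valid cells of `m_b`, a model is fitted with the same feature classes,
#' penalty, predictor stack, and shared background sample as the real fits
#' (isolating the randomization to the occurrence points), its prediction is
#' normalized, and D and I against species A's normalized surface are
#' recorded. The null hypothesis of niche similarity is rejected when the
#' observed D (or I) between the two real models falls below the 5th
#' percentile of the null distribution (one-tailed; low similarity rejects).
#'
#' @param map_a,map_b The two species' real median suitability
#'   [env_layer()]s; the observed D and I compare these.
#' @param m_b [calibration_region()] of the species whose background supplies
#'   the random points (`NULL` = whole grid).
#' @param n_points_b Number of random points per replicate (the real
#'   occurrence count of species B).
#' @param pc_stack Predictor [env_stack()].
#' @param background Shared background cells for all fits.
#' @param n_replicates Number of random replicates (default 100).
#' @param seed Integer seed.
#' @param spec,beta,tol Model settings, shared with the real fits.
#' @return Object of class `overlap_result`: observed and null D and I, their
#'   5th percentiles (linear interpolation of order statistics), the
#'   one-tailed decisions, and the empirical percentile rank of the observed
#'   values.
#' @export
background_similarity_test <- function(map_a, map_b, m_b, n_points_b, pc_stack,
                                       background, n_replicates = 100, seed = 1,
                                       spec = maxent_features(), beta = 1,
                                       tol = 1e-6) {
  mask <- !is.na(map_a$values) & !is.na(map_b$values)
  pa <- normalize_surface(map_a, mask)
  pb <- normalize_surface(map_b, mask)
  D_obs <- schoener_D(pa, pb)
  I_obs <- hellinger_I(pa, pb)
  cells <- which(valid_mask(pc_stack) & region_mask(pc_stack$grid, m_b))
  if (!length(cells)) stop("region error: m_b holds no valid cells")
  null_D <- numeric(0); null_I <- numeric(0); n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    pts <- with_seed(sub_seed(seed, 4, r),
                     sample(cells, n_points_b, replace = TRUE))
    res <- tryCatch({
      m <- fit_maxent_cells(pts, background, pc_stack, spec = spec,
                            beta = beta, tol = tol,
                            replicate_id = sprintf("null%03d", r))
      pr <- normalize_surface(predict(m, pc_stack), mask)
      c(schoener_D(pa, pr), hellinger_I(pa, pr))
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L
    else { null_D <- c(null_D, res[1]); null_I <- c(null_I, res[2]) }
  }
  if (n_failed > 0.2 * n_replicates)
    stop("test error: ", n_failed, " of ", n_replicates,
         " null replicates failed to fit")
  q5_D <- unname(stats::quantile(null_D, 0.05, type = 7))
  q5_I <- unname(stats::quantile(null_I, 0.05, type = 7))
  structure(list(
    D_observed = D_obs, I_observed = I_obs,
    null_D = null_D, null_I = null_I,
    percentile_5_D = q5_D, percentile_5_I = q5_I,
    reject_D = D_obs < q5_D, reject_I = I_obs < q5_I,
    rank_D = mean(null_D < D_obs), rank_I = mean(null_I < I_obs),
    n_replicates = length(null_D), n_failed = n_failed
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "background similarity test (%d replicates):\n  D = %.4f (5th pct %.4f) -> %s\n  I = %.4f (5th pct %.4f) -> %s\n",
    x$n_replicates, x$D_observed, x$percentile_5_D,
    if (x$reject_D) "reject similarity" else "fail to reject",
    x$I_observed, x$percentile_5_I,
    if (x$reject_I) "reject similarity" else "fail to reject"))
  invisible(x)
}
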