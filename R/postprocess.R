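#' Threshold a suitability map at a maximum allowable omission rate
#'
#' The cutoff `tau` is the largest suitability value `v` observed at a
#' calibration point such that the fraction of calibration points with
#' suitability strictly below `v` does not exceed `E` — i.e. up to a fraction
#' `E` of occurrences (assumed to carry coordinate or environmental error) may
#' be omitted, and no higher cutoff would respect that bound. The binary map
#' is `suitability >= tau`, so points exactly at the cutoff are predicted
#' present.
#'
#' @param median_map Suitability [env_layer()].
#' @param calibration Calibration occurrence set; points off-grid or on nodata
#'   cells are dropped with a warning.
#' @param E Allowed omission fraction (default 0.05).
#' @return List with `threshold` (fields `E`, `tau`, `omission`) and `binary`
#'   (0/1 [env_layer()], nodata preserved).
#' @export
threshold_E <- function(median_map, calibration, E = 0.05) {
  idx <- cell_index(median_map$grid, calibration$longitude,
                    calibration$latitude)
  s <- rep(NA_real_, length(idx))
  s[!is.na(idx)] <- median_map$values[idx[!is.na(idx)]]
  if (any(is.na(s)))
    warning(sum(is.na(s)), " calibration points off-grid or on nodata dropped")
  s <- s[!is.na(s)]
  if (!length(s)) stop("threshold error: no calibration points on valid cells")
  cand <- sort(unique(s))
  below <- vapply(cand, function(v) mean(s < v), numeric(1))
  tau <- max(cand[below <= E])
  binary <- median_map$values
  binary[!is.na(binary)] <- as.numeric(binary[!is.na(binary)] >= tau)
  list(threshold = list(E = E, tau = tau, omission = mean(s < tau)),
       binary = env_layer(binary, median_map$grid, "binary"))
}

#' Ensemble per-GCM median predictions for one scenario
#'
#' Computes the per-cell median across the single-GCM medians (the
#' medians-of-medians summary), the per-cell range across GCMs (the future
#' uncertainty index for the RCP), and the binary map obtained by applying the
#' *present-day* threshold `tau` to the ensemble median.
#'
#' @param per_gcm_medians List of suitability [env_layer()]s on one grid.
#' @param tau Present-day suitability cutoff from [threshold_E()].
#' @param rcp,period Optional scenario labels carried through.
#' @return Object of class `ensemble_product` with `per_gcm_medians`,
#'   `ensemble_median`, `uncertainty_range`, `binary`, `rcp`, `period`.
#' @export
ensemble_future <- function(per_gcm_medians, tau, rcp = NA, period = NA) {
  if (!length(per_gcm_medians)) stop("need at least one GCM map")
  g <- per_gcm_medians[[1]]$grid
  for (m in per_gcm_medians)
    if (!grid_equal(m$grid, g)) stop("schema error: GCM maps on different grids")
  arr <- array(unlist(lapply(per_gcm_medians, function(m) m$values)),
               dim = c(g$n_rows, g$n_cols, length(per_gcm_medians)))
  med <- apply(arr, c(1, 2), stats::median)
  rng <- apply(arr, c(1, 2), max) - apply(arr, c(1, 2), min)
  binary <- med
  binary[!is.na(binary)] <- as.numeric(binary[!is.na(binary)] >= tau)
  structure(list(rcp = rcp, period = period,
                 per_gcm_medians = per_gcm_medians,
                 ensemble_median = env_layer(med, g, "ensemble_median"),
                 uncertainty_range = env_layer(rng, g, "gcm_range"),
                 binary = env_layer(binary, g, "ensemble_binary")),
            class = "ensemble_product")
}

#' Suitable-area change between two binary maps
#'
#' Areas are cell counts. Both conventions of the percentage change are
#' reported: relative to the present suitable area, and relative to all valid
#' cells of the grid.
#'
#' @param present_binary,future_binary 0/1 [env_layer()]s on one grid.
#' @return List with `cells_present`, `cells_future`, `percent_relative`
#'   (`NA` when no present suitable area exists), `percent_of_total`.
#' @export
area_change <- function(present_binary, future_binary) {
  if (!grid_equal(present_binary$grid, future_binary$grid))
    stop("schema error: grids differ")
  p <- present_binary$values; f <- future_binary$values
  a_p <- sum(p == 1, na.rm = TRUE)
  a_f <- sum(f == 1, na.rm = TRUE)
  n_valid <- sum(!is.na(p))
  list(cells_present = a_p, cells_future = a_f,
       percent_relative = if (a_p > 0) 100 * (a_f - a_p) / a_p else NA_real_,
       percent_of_total = 100 * (a_f - a_p) / n_valid)
}

#' Build a present/future agreement (stability) map
#'
#' Classifies every valid cell by present-day suitability, ensemble-future
#' suitability, and the number `G` of GCMs individually predicting the cell
#' suitable: 1 = stable (suitable now and in the ensemble future), 2 = future
#' gain with agreement of all GCMs, 3 = future gain with partial (low)
#' agreement, 4 = present-only (loss), 0 = unsuitable in both. The codes
#' partition the valid cells.
#'
#' @param present_binary 0/1 [env_layer()].
#' @param per_gcm_binaries List of 0/1 [env_layer()]s, one per GCM, each
#'   obtained by applying the present-day threshold to that GCM's median.
#' @param ensemble_binary 0/1 [env_layer()] from [ensemble_future()].
#' @return An [env_layer()] of integer codes 0-4 (class kept numeric; nodata
#'   preserved).
#' @export
stability_map <- function(present_binary, per_gcm_binaries, ensemble_binary) {
  g <- present_binary$grid
  for (m in c(per_gcm_binaries, list(ensemble_binary)))
    if (!grid_equal(m$grid, g)) stop("schema error: grids differ")
  n_gcm <- length(per_gcm_binaries)
  G <- Reduce(`+`, lapply(per_gcm_binaries, function(m) m$values))
  p <- present_binary$values
  f <- ensemble_binary$values
  code <- matrix(NA_real_, g$n_rows, g$n_cols)
  valid <- !is.na(p)
  code[valid] <- 0
  code[valid & p == 1 & f == 1] <- 1
  code[valid & p == 0 & G == n_gcm] <- 2
  code[valid & p == 0 & G > 0 & G < n_gcm] <- 3
  code[valid & p == 1 & f == 0] <- 4
  env_layer(code, g, "stability")
}
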