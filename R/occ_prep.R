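#' Drop low-precision occurrence records
#'
#' Keeps only records with exact coordinates (`precision_flag == "exact"`),
#' mirroring the quality-control rule that positional uncertainty must not
#' exceed the analysis pixel.
#'
#' @param occ An occurrence set at stage `"raw"`.
#' @return The filtered set at stage `"precise"`; the counts log gains the new
#'   total.
#' @export
filter_precision <- function(occ) {
  stopifnot(occ_stage(occ) == "raw")
  out <- occ[occ$precision_flag == "exact", , drop = FALSE]
  if (nrow(out) == 0) warning("no exact-coordinate records remain")
  new_occurrence_set(as.data.frame(out), "precise", counts_log(occ))
}

#' Collapse exact duplicate records
#'
#' Two records are duplicates when they share `(species, longitude, latitude)`
#' exactly (bitwise); the first record in input order is kept. Records
#' differing by any amount, however small, are both retained.
#'
#' @param occ An occurrence set at stage `"precise"`.
#' @return The deduplicated set at stage `"unique"`.
#' @export
deduplicate <- function(occ) {
  stopifnot(occ_stage(occ) == "precise")
  key <- paste(occ$species, sprintf("%.17g", occ$longitude),
               sprintf("%.17g", occ$latitude), sep = "\r")
  out <- occ[!duplicated(key), , drop = FALSE]
  new_occurrence_set(as.data.frame(out), "unique", counts_log(occ))
}

#' Thin records to one per grid cell per species
#'
#' Implements the distance filter literally as pixel uniqueness: among unique
#' records, at most one per occupied cell per species survives (the first in
#' input order). Records falling outside the grid or on nodata cells are
#' dropped and counted in the `n_offgrid` attribute.
#'
#' @param occ An occurrence set at stage `"unique"` (a `"thinned"` set is
#'   accepted too, making the operation idempotent).
#' @param grid A [raster_grid()] or an [env_stack()] (whose nodata mask is then
#'   honoured).
#' @return The thinned set at stage `"thinned"`.
#' @export
thin_to_grid <- function(occ, grid) {
  stopifnot(occ_stage(occ) %in% c("unique", "thinned"))
  mask <- NULL
  if (inherits(grid, "env_stack")) {
    mask <- valid_mask(grid)
    grid <- grid$grid
  }
  idx <- cell_index(grid, occ$longitude, occ$latitude)
  on_grid <- !is.na(idx)
  if (!is.null(mask)) {
    on_valid <- rep(FALSE, length(idx))
    on_valid[on_grid] <- mask[idx[on_grid]]
    on_grid <- on_grid & on_valid
  }
  key <- paste(occ$species, idx, sep = "\r")
  keep <- on_grid & !duplicated(key)
  out <- new_occurrence_set(as.data.frame(occ[keep, , drop = FALSE]),
                            "thinned", counts_log(occ))
  attr(out, "n_offgrid") <- sum(!on_grid)
  out
}

#' Randomly split records into calibration and evaluation halves
#'
#' A uniform random partition without replacement: `ceiling(fraction * n)`
#' records go to calibration, the remainder to evaluation. The two halves are
#' disjoint, their union is the input, and the partition is reproducible from
#' the seed.
#'
#' @param occ An occurrence set at stage `"thinned"`.
#' @param fraction Calibration fraction in `(0, 1)` (default 0.5).
#' @param seed Integer seed.
#' @return List with elements `calibration` and `evaluation`.
#' @export
split_calibration <- function(occ, fraction = 0.5, seed = 1) {
  stopifnot(occ_stage(occ) == "thinned")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(occ)
  if (n < 2) stop("split error: need at least 2 records")
  k <- ceiling(fraction * n)
  cal_i <- sort(with_seed(seed, sample.int(n, k)))
  cal <- new_occurrence_set(as.data.frame(occ[cal_i, , drop = FALSE]),
                            "calibration", counts_log(occ))
  ev <- new_occurrence_set(as.data.frame(occ[-cal_i, , drop = FALSE]),
                           "evaluation", counts_log(occ))
  list(calibration = cal, evaluation = ev)
}
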