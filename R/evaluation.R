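#' Partial-ROC bootstrap significance test
#'
#' Evaluates a continuous suitability map against withheld occurrences in the
#' high-sensitivity region only. Per iteration: (1) resample
#' `ceiling(resample_fraction * n)` test points with replacement; (2) over
#' `n_bins` equal-width suitability cutoffs `t` compute sensitivity
#' (fraction of resampled points with suitability `>= t`) and the proportional
#' predicted area PPA (fraction of valid cells with suitability `>= t`); (3)
#' restrict the curve to sensitivity `>= 1 - E`, interpolating the exact
#' boundary crossing; (4) integrate sensitivity over PPA by trapezoid; (5)
#' divide by the null partial area, the area under the identity line
#' (sensitivity = PPA) over the same PPA range. A ratio above 1 means the
#' model concentrates occurrences better than random; the p-value is the
#' fraction of iterations with ratio `<= 1`.
#'
#' @param median_map Suitability [env_layer()].
#' @param test_occ Withheld occurrence set; at least 10 points must fall on
#'   valid cells.
#' @param E Allowed omission (default 0.05).
#' @param n_iterations Bootstrap iterations (default 1000).
#' @param resample_fraction Fraction of test points per iteration.
#' @param n_bins Number of equal-width cutoff bins on `[0, 1]`.
#' @param seed Integer seed.
#' @return Object of class `proc_result` with the ratio list, summary
#'   statistics, `n_ns` (iterations with ratio `<= 1`) and `p_value`.
#' @export
partial_roc <- function(median_map, test_occ, E = 0.05, n_iterations = 1000,
                        resample_fraction = 0.5, n_bins = 100, seed = 1) {
  idx <- cell_index(median_map$grid, test_occ$longitude, test_occ$latitude)
  s_test <- rep(NA_real_, length(idx))
  s_test[!is.na(idx)] <- median_map$values[idx[!is.na(idx)]]
  s_test <- s_test[!is.na(s_test)]
  if (length(s_test) < 10)
    stop("need at least 10 test points on valid cells, got ", length(s_test))
  s_cells <- median_map$values[!is.na(median_map$values)]
  cutoffs <- seq(0, 1, length.out = n_bins + 1)
  ppa <- vapply(cutoffs, function(t) mean(s_cells >= t), numeric(1))
  k <- ceiling(resample_fraction * length(s_test))
  ratios <- with_seed(seed, vapply(seq_len(n_iterations), function(i) {
    ss <- sample(s_test, k, replace = TRUE)
    sens <- vapply(cutoffs, function(t) mean(ss >= t), numeric(1))
    proc_ratio(sens, ppa, E)
  }, numeric(1)))
  bad <- is.na(ratios)
  if (any(bad)) {
    warning(sum(bad), " iterations had a degenerate partial-ROC curve")
    ratios <- ratios[!bad]
  }
  n_ns <- sum(ratios <= 1 + 1e-12)  # tolerance guards the degenerate ratio-1 case
  structure(list(E = E, n_iterations = length(ratios), ratios = ratios,
                 min = min(ratios), max = max(ratios),
                 mean = mean(ratios), median = stats::median(ratios),
                 n_ns = n_ns, p_value = n_ns / length(ratios)),
            class = "proc_result")
}

# partial AUC ratio for one sensitivity curve against the cell PPA curve;
# sens and ppa are evaluated on the same ascending cutoff grid
proc_ratio <- function(sens, ppa, E) {
  smin <- 1 - E
  keep <- sens >= smin
  if (!any(keep)) return(NA_real_)
  x <- ppa[keep]
  y <- sens[keep]
  j <- max(which(keep))
  if (j < length(sens) && sens[j] > smin && sens[j + 1] < sens[j]) {
    # interpolate the exact crossing of the sensitivity bound
    frac <- (smin - sens[j]) / (sens[j + 1] - sens[j])
    x <- c(x, ppa[j] + frac * (ppa[j + 1] - ppa[j]))
    y <- c(y, smin)
  }
  if (length(x) < 2) return(NA_real_)
  # cutoffs ascend, so PPA descends; integrate sens dPPA
  pauc_model <- sum((x[-length(x)] - x[-1]) * (y[-length(y)] + y[-1]) / 2)
  pauc_null <- (max(x)^2 - min(x)^2) / 2
  if (pauc_null <= 0) return(NA_real_)
  pauc_model / pauc_null
}

#' @export
print.proc_result <- function(x, ...) {
  cat(sprintf(
    "partial ROC (E = %g%%, %d iterations): ratio mean %.3f [%.3f, %.3f], median %.3f; %d ratios <= 1; p = %.4g\n",
    100 * x$E, x$n_iterations, x$mean, x$min, x$max, x$median, x$n_ns,
    x$p_value))
  invisible(x)
}

#' One-tailed cumulative binomial test on independent records
#'
#' Tests whether the number of independent occurrence records falling on cells
#' predicted suitable exceeds the chance expectation given by the proportional
#' coverage `p` of the evaluated region by the thresholded map. The exact
#' upper binomial tail `P(X >= s)` is used (no normal approximation).
#'
#' @param binary 0/1 [env_layer()] from [threshold_E()].
#' @param independent_occ Independent occurrence set; records off-grid or on
#'   nodata are dropped and counted.
#' @return Object of class `binomial_result` with `n`, `s`, `p`, `p_value`,
#'   and `n_dropped`.
#' @export
binomial_test <- function(binary, independent_occ) {
  idx <- cell_index(binary$grid, independent_occ$longitude,
                    independent_occ$latitude)
  b <- rep(NA_real_, length(idx))
  b[!is.na(idx)] <- binary$values[idx[!is.na(idx)]]
  n_dropped <- sum(is.na(b))
  b <- b[!is.na(b)]
  if (!length(b)) stop("evaluation error: no independent records on valid cells")
  v <- binary$values[!is.na(binary$values)]
  p <- mean(v == 1)
  s <- sum(b == 1)
  n <- length(b)
  structure(list(n = n, s = s, p = p,
                 p_value = stats::pbinom(s - 1, n, p, lower.tail = FALSE),
                 n_dropped = n_dropped),
            class = "binomial_result")
}

#' @export
print.binomial_result <- function(x, ...) {
  cat(sprintf(
    "binomial test: %d/%d records on suitable cells (coverage p = %.3f); one-tailed P = %.4g\n",
    x$s, x$n, x$p, x$p_value))
  invisible(x)
}
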