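#' Drop named layers from a stack
#'
#' The default exclusion set removes the four bioclimatic variables with known
#' spatial artifacts (bio8, bio9, bio18, bio19), leaving 15 of the 19.
#'
#' @param stack An [env_stack()].
#' @param excluded Character vector of layer names to drop; every name must
#'   exist in the stack.
#' @return The stack without the excluded layers.
#' @export
exclude_layers <- function(stack, excluded = c("bio8", "bio9", "bio18", "bio19")) {
  unknown <- setdiff(excluded, stack_names(stack))
  if (length(unknown))
    stop("unknown layer name(s) in exclusion set: ",
         paste(unknown, collapse = ", "))
  keep <- setdiff(stack_names(stack), excluded)
  if (!length(keep)) stop("exclusion set would remove all layers")
  env_stack(stack$layers[keep], stack$grid, scenario_tag = stack$scenario_tag)
}

#' Fit a correlation-matrix PCA on a present-day stack
#'
#' Each layer is z-scored using its mean and standard deviation over non-nodata
#' cells (bioclimatic variables have incommensurate units, so correlation
#' rather than covariance structure is decomposed). Components are ordered by
#' decreasing variance, and each loading column is sign-fixed so its
#' largest-magnitude entry is positive, making results reproducible across
#' linear-algebra backends.
#'
#' @param stack An [env_stack()] with at least two layers and more non-nodata
#'   cells than layers.
#' @return Object of class `pca_transform` with fields `layer_names`, `means`,
#'   `sds`, `loadings` (layers x components, orthonormal), `eigenvalues`, and
#'   `variance_fraction`.
#' @export
fit_pca <- function(stack) {
  nm <- stack_names(stack)
  if (length(nm) < 2) stop("need at least 2 layers for PCA")
  idx <- which(valid_mask(stack))
  if (length(idx) < length(nm) + 1)
    stop("need more non-nodata cells than layers")
  X <- stack_values_at(stack, idx)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degeneracy error: constant layer(s): ",
         paste(nm[sds == 0], collapse = ", "))
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  L <- pr$rotation
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  ev <- pr$sdev^2
  structure(list(layer_names = nm, means = pr$center, sds = pr$scale,
                 loadings = L, eigenvalues = ev,
                 variance_fraction = ev / sum(ev)),
            class = "pca_transform")
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("pca_transform: %d layers; leading variance fractions: %s\n",
              length(x$layer_names),
              paste(sprintf("%.3f", utils::head(x$variance_fraction, 5)),
                    collapse = " ")))
  invisible(x)
}

#' Project a stack onto present-day principal components
#'
#' Every cell vector is centered and scaled by the *present-day* statistics
#' stored in the transform and projected onto its loadings — the mechanism by
#' which future-climate stacks are expressed in the axes fitted on present-day
#' data. Nodata propagates.
#'
#' @param stack An [env_stack()] whose layer names equal the transform's (any
#'   order).
#' @param pca A `pca_transform` from [fit_pca()].
#' @param n_components How many leading components to keep (default 8, which
#'   in the bioclimatic setting carries >99.99% of total variance).
#' @return An [env_stack()] of `PC1 ... PCk` layers with the same scenario tag.
#' @export
transform_stack <- function(stack, pca, n_components = 8) {
  if (!setequal(stack_names(stack), pca$layer_names))
    stop("schema error: stack layer names do not match the PCA transform")
  k <- n_components
  if (k < 1 || k > ncol(pca$loadings))
    stop("n_components must be between 1 and ", ncol(pca$loadings))
  idx <- which(valid_mask(stack))
  X <- stack_values_at(stack, idx)[, pca$layer_names, drop = FALSE]
  Z <- sweep(sweep(X, 2, pca$means, "-"), 2, pca$sds, "/")
  P <- Z %*% pca$loadings[, seq_len(k), drop = FALSE]
  g <- stack$grid
  layers <- lapply(seq_len(k), function(j) {
    m <- matrix(NA_real_, g$n_rows, g$n_cols)
    m[idx] <- P[, j]
    m
  })
  names(layers) <- sprintf("PC%d", seq_len(k))
  env_stack(layers, g, scenario_tag = stack$scenario_tag)
}

#' Number of components needed to reach a variance target
#'
#' @param pca A `pca_transform`.
#' @param variance_target Fraction in `(0, 1]`.
#' @return The smallest `k` whose cumulative variance fraction reaches the
#'   target.
#' @export
select_components <- function(pca, variance_target) {
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]")
  as.integer(which(cumsum(pca$variance_fraction) >= variance_target - 1e-12)[1])
}
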