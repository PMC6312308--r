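#' Specify the feature classes of the maximum-entropy model
#'
#' Linear features are always included; quadratic (per-layer squares) and
#' product (pairwise interactions) features are optional. On smooth principal
#' component inputs, linear + quadratic features span unimodal Gaussian-like
#' responses; hinge and threshold features are deliberately not offered, which
#' keeps the fitting problem convex and the model identifiable.
#'
#' @param classes Subset of `c("linear", "quadratic", "product")`.
#' @return Object of class `feature_spec`.
#' @export
maxent_features <- function(classes = c("linear", "quadratic")) {
  classes <- union("linear", match.arg(classes,
                                       c("linear", "quadratic", "product"),
                                       several.ok = TRUE))
  structure(list(classes = classes), class = "feature_spec")
}

# expand a cells x layers matrix into the model's feature columns
expand_features <- function(X, classes) {
  nm <- colnames(X)
  out <- X
  if ("quadratic" %in% classes) {
    Q <- X^2
    colnames(Q) <- paste0(nm, "^2")
    out <- cbind(out, Q)
  }
  if ("product" %in% classes && ncol(X) > 1) {
    pairs <- utils::combn(seq_len(ncol(X)), 2)
    P <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
    colnames(P) <- paste0(nm[pairs[1, ]], "*", nm[pairs[2, ]])
    out <- cbind(out, P)
  }
  out
}

#' Sample background cells from the accessible area
#'
#' Draws `n` distinct non-nodata cells uniformly without replacement from the
#' intersection of the grid with the calibration region `m`. If fewer than `n`
#' cells are available, all of them are returned with a warning.
#'
#' @param pc_stack An [env_stack()] (the nodata mask is honoured).
#' @param m A [calibration_region()], or `NULL` for the whole grid.
#' @param n Background size (default 10000, the conventional presence-
#'   background default).
#' @param seed Integer seed.
#' @return Sorted integer vector of linear cell indices.
#' @export
sample_background <- function(pc_stack, m = NULL, n = 10000, seed = 1) {
  cells <- which(valid_mask(pc_stack) & region_mask(pc_stack$grid, m))
  if (!length(cells))
    stop("region error: calibration region contains no non-nodata cells")
  if (length(cells) <= n) {
    if (length(cells) < n)
      warning("region holds only ", length(cells), " cells; using all of them")
    return(cells)
  }
  sort(with_seed(seed, sample(cells, n)))
}

# ---- L1-regularized Gibbs (maximum-entropy) fit -----------------------------

# objective: -mean(Fp w) + log mean exp(Fb w) + s * ||w||_1  (standardized features)
gibbs_objective <- function(w, pbar, Fb, s) {
  eta <- drop(Fb %*% w)
  a <- max(eta)
  -sum(pbar * w) + a + log(mean(exp(eta - a))) + s * sum(abs(w))
}

# coordinate descent on the local quadratic model
# minimize g'(z-w) + 0.5 (z-w)' H (z-w) + s ||z||_1
cd_quadratic_l1 <- function(w, g, H, s, sweeps = 200, tol = 1e-12) {
  z <- w
  r <- g  # r = g + H (z - w)
  d <- length(w)
  hjj <- diag(H)
  for (it in seq_len(sweeps)) {
    delta_max <- 0
    for (j in seq_len(d)) {
      b <- hjj[j] * z[j] - r[j]
      znew <- sign(b) * max(abs(b) - s, 0) / hjj[j]
      if (znew != z[j]) {
        r <- r + H[, j] * (znew - z[j])
        delta_max <- max(delta_max, abs(znew - z[j]))
        z[j] <- znew
      }
    }
    if (delta_max < tol) break
  }
  z
}

# proximal Newton solver; returns standardized-space weights
fit_l1_gibbs <- function(Fp, Fb, s, tol = 1e-6, max_iter = 10000, init = NULL) {
  d <- ncol(Fb)
  pbar <- colMeans(Fp)
  w <- if (is.null(init)) rep(0, d) else rep_len(init, d)
  kkt <- Inf
  for (iter in seq_len(max_iter)) {
    eta <- drop(Fb %*% w)
    a <- max(eta)
    q <- exp(eta - a)
    q <- q / sum(q)
    mu <- drop(crossprod(Fb, q))
    g <- -pbar + mu
    kkt <- max(ifelse(w != 0, abs(g + s * sign(w)), pmax(abs(g) - s, 0)))
    if (kkt <= tol) return(list(w = w, kkt = kkt, iterations = iter))
    H <- crossprod(Fb * sqrt(q)) - tcrossprod(mu)
    diag(H) <- diag(H) + 1e-10
    z <- cd_quadratic_l1(w, g, H, s)
    dir <- z - w
    decr <- sum(g * dir) + s * (sum(abs(z)) - sum(abs(w)))
    f0 <- gibbs_objective(w, pbar, Fb, s)
    t <- 1
    repeat {
      if (gibbs_objective(w + t * dir, pbar, Fb, s) <= f0 + 0.25 * t * decr)
        break
      t <- t / 2
      if (t < 1e-12) break
    }
    if (t < 1e-12) break  # no progress possible at machine precision
    w <- w + t * dir
  }
  # re-check optimality at exit
  eta <- drop(Fb %*% w); a <- max(eta); q <- exp(eta - a); q <- q / sum(q)
  g <- -pbar + drop(crossprod(Fb, q))
  kkt <- max(ifelse(w != 0, abs(g + s * sign(w)), pmax(abs(g) - s, 0)))
  if (kkt > tol * 100)
    stop("fit error: optimizer did not converge; final KKT residual ",
         format(kkt))
  list(w = w, kkt = kkt, iterations = max_iter)
}

# fit from presence / background cell indices
fit_maxent_cells <- function(pres_idx, bg_idx, pc_stack, spec = maxent_features(),
                             beta = 1, tol = 1e-6, max_iter = 10000,
                             m_region = NULL, replicate_id = NA_character_,
                             init = NULL) {
  if (length(pres_idx) < 10)
    stop("data error: need at least 10 presences on non-nodata cells, got ",
         length(pres_idx))
  Xp <- stack_values_at(pc_stack, pres_idx)
  Xb <- stack_values_at(pc_stack, bg_idx)
  calib_ranges <- rbind(min = pmin(apply(Xp, 2, min), apply(Xb, 2, min)),
                        max = pmax(apply(Xp, 2, max), apply(Xb, 2, max)))
  Fp <- expand_features(Xp, spec$classes)
  Fb <- expand_features(Xb, spec$classes)
  ctr <- colMeans(Fb)
  scl <- apply(Fb, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Fp <- sweep(sweep(Fp, 2, ctr, "-"), 2, scl, "/")
  Fb <- sweep(sweep(Fb, 2, ctr, "-"), 2, scl, "/")
  # MaxEnt-style penalty: beta scaled by feature sd (1 after standardization)
  # and by 1/sqrt(m), so regularization relaxes as presences accumulate
  s <- beta / sqrt(length(pres_idx))
  fit <- fit_l1_gibbs(Fp, Fb, s, tol = tol, max_iter = max_iter, init = init)
  names(fit$w) <- colnames(Fb)
  eta_b <- drop(Fb %*% fit$w)
  a <- max(eta_b)
  structure(list(
    feature_spec = spec, layer_names = stack_names(pc_stack),
    weights = fit$w, feature_center = ctr, feature_scale = scl,
    log_normalizer = a + log(mean(exp(eta_b - a))),
    calib_ranges = calib_ranges, m_region = m_region,
    replicate_id = replicate_id, beta = beta, penalty = s,
    n_presences = length(pres_idx), kkt = fit$kkt,
    iterations = fit$iterations
  ), class = "maxent_model")
}

#' Fit the maximum-entropy presence-background model
#'
#' Estimates a Gibbs density over the background: feature weights minimize the
#' convex objective
#' `-(1/m) sum_presences eta(x) + log((1/B) sum_background exp(eta(x)))`
#' plus an L1 penalty `(beta / sqrt(m)) * sum_j s_j |lambda_j|` with `s_j` the
#' feature's background standard deviation, the estimand of MaxEnt's raw
#' output. Solved by proximal Newton with an inner coordinate descent, to a
#' KKT residual of `tol`. Training environmental ranges are recorded per layer
#' for the no-extrapolation rule at prediction time.
#'
#' @param presences An occurrence set; records are mapped to cells, and
#'   records off-grid or on nodata cells are dropped. At least 10 must remain.
#' @param background Integer cell indices from [sample_background()] (presence
#'   cells may also appear in the background).
#' @param pc_stack The [env_stack()] of predictor layers (typically principal
#'   components).
#' @param spec A [maxent_features()] specification.
#' @param beta Regularization multiplier (default 1).
#' @param tol KKT convergence tolerance.
#' @param max_iter Iteration cap.
#' @param m_region Optional [calibration_region()] recorded with the model.
#' @param replicate_id Optional label.
#' @return Object of class `maxent_model`.
#' @export
fit_maxent <- function(presences, background, pc_stack,
                       spec = maxent_features(), beta = 1,
                       tol = 1e-6, max_iter = 10000,
                       m_region = NULL, replicate_id = NA_character_) {
  idx <- cell_index(pc_stack$grid, presences$longitude, presences$latitude)
  mask <- valid_mask(pc_stack)
  ok <- !is.na(idx)
  ok[ok] <- mask[idx[ok]]
  fit_maxent_cells(idx[ok], background, pc_stack, spec = spec, beta = beta,
                   tol = tol, max_iter = max_iter, m_region = m_region,
                   replicate_id = replicate_id)
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model (%s features on %d layers): %d/%d nonzero weights, m = %d\n",
    paste(x$feature_spec$classes, collapse = "+"), length(x$layer_names),
    sum(x$weights != 0), length(x$weights), x$n_presences))
  invisible(x)
}

#' Predict suitability from a fitted model
#'
#' Computes the Gibbs intensity `exp(eta(x))` on every valid cell and rescales
#' by its maximum over valid in-range cells, giving suitability in `[0, 1]`
#' with the maximum exactly 1. Extrapolation is deactivated: any cell with at
#' least one predictor outside the model's training range gets suitability 0
#' and is flagged in the `novelty` attribute (a logical matrix). Values are
#' never clamped into range.
#'
#' @param object A `maxent_model`.
#' @param pc_stack An [env_stack()] with the model's layer names (any scenario).
#' @param ... Unused.
#' @return An [env_layer()] of suitability with attribute `novelty`.
#' @export
predict.maxent_model <- function(object, pc_stack, ...) {
  if (!setequal(stack_names(pc_stack), object$layer_names))
    stop("schema error: stack layers do not match the model's")
  g <- pc_stack$grid
  idx <- which(valid_mask(pc_stack))
  X <- stack_values_at(pc_stack, idx)[, object$layer_names, drop = FALSE]
  rng <- object$calib_ranges
  in_range <- rep(TRUE, nrow(X))
  for (j in seq_len(ncol(X)))
    in_range <- in_range & X[, j] >= rng["min", j] & X[, j] <= rng["max", j]
  FF <- expand_features(X, object$feature_spec$classes)
  FF <- sweep(sweep(FF, 2, object$feature_center, "-"), 2,
              object$feature_scale, "/")
  eta <- drop(FF %*% object$weights)
  suit <- numeric(length(idx))
  if (any(in_range)) {
    m <- max(eta[in_range])
    suit[in_range] <- exp(eta[in_range] - m)
  }
  vals <- matrix(NA_real_, g$n_rows, g$n_cols)
  vals[idx] <- suit
  nov <- matrix(FALSE, g$n_rows, g$n_cols)
  nov[idx] <- !in_range
  out <- env_layer(vals, g, name = "suitability")
  attr(out, "novelty") <- nov
  out
}

#' Fit bootstrapped model replicates and summarize them
#'
#' Each replicate draws `ceiling(train_fraction * n)` presences with
#' replacement from the calibration records (a bootstrap of 50% of calibration
#' points by default), using a deterministic replicate-specific sub-seed, and
#' is fitted against one shared background sample so replicate spread reflects
#' occurrence resampling only. Per-cell median and range (max - min, the
#' replicate uncertainty index) maps are computed across replicates.
#'
#' @param calibration Calibration occurrence set (non-empty).
#' @param pc_stack Predictor [env_stack()].
#' @param n_replicates Number of bootstrap replicates (default 10).
#' @param train_fraction Fraction of calibration points per replicate.
#' @param seed Integer master seed.
#' @param background Shared background cells from [sample_background()].
#' @param ... Passed to [fit_maxent()] (`spec`, `beta`, `tol`, ...).
#' @return Object of class `replicate_set`: list with `models`, `replicates`
#'   (suitability layers), `median_map`, and `range_map`.
#' @export
fit_replicates <- function(calibration, pc_stack, n_replicates = 10,
                           train_fraction = 0.5, seed = 1, background, ...) {
  n <- nrow(calibration)
  if (n < 1) stop("calibration set is empty")
  idx_all <- cell_index(pc_stack$grid, calibration$longitude,
                        calibration$latitude)
  mask <- valid_mask(pc_stack)
  ok <- !is.na(idx_all)
  ok[ok] <- mask[idx_all[ok]]
  idx_all <- idx_all[ok]
  k <- ceiling(train_fraction * length(idx_all))
  models <- vector("list", n_replicates)
  maps <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    boot <- with_seed(sub_seed(seed, 3, i),
                      sample(idx_all, k, replace = TRUE))
    models[[i]] <- tryCatch(
      fit_maxent_cells(boot, background, pc_stack,
                       replicate_id = sprintf("rep%02d", i), ...),
      error = function(e) stop("replicate ", i, ": ", conditionMessage(e)))
    maps[[i]] <- predict(models[[i]], pc_stack)
  }
  g <- pc_stack$grid
  arr <- array(unlist(lapply(maps, function(m) m$values)),
               dim = c(g$n_rows, g$n_cols, n_replicates))
  med <- apply(arr, c(1, 2), stats::median)
  rng <- apply(arr, c(1, 2), max) - apply(arr, c(1, 2), min)
  structure(list(models = models, replicates = maps,
                 median_map = env_layer(med, g, "median_suitability"),
                 range_map = env_layer(rng, g, "replicate_range")),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("replicate_set: %d bootstrapped replicates\n",
              length(x$replicates)))
  invisible(x)
}
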