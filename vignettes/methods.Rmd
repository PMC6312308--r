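---
title: "Methods: presence-background niche modeling on a virtual world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background niche modeling on a virtual world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Ecological niche models (ENMs) estimate where a species could persist from
two ingredients: georeferenced occurrence records and gridded environmental
layers. For invasive disease vectors such as *Aedes* mosquitoes the standard
workflow is: clean the occurrence compilation, reduce a correlated
bioclimatic layer set by PCA, fit a maximum-entropy presence-background model
within a hypothesized accessible area *M*, threshold the continuous
prediction at an allowed omission rate, project the model onto an ensemble of
future-climate scenarios (GCM x RCP x period), and test both predictive
significance (partial ROC, cumulative binomial) and between-species niche
overlap (Schoener's D, Hellinger's I, background-similarity randomization).

`nichecast` implements that entire chain as composable functions, and pairs
it with a synthetic *virtual world* whose true suitability is known, so every
stage can be validated against ground truth rather than inspected by eye.

# The model core

The model is the Gibbs density that maximum-entropy presence-background
estimation targets. With feature vector $f(x)$ over the environment of cell
$x$, weights $\lambda$, presences $x_1..x_m$ and background cells
$b_1..b_B$, the fit minimizes the convex objective

$$
-\frac1m \sum_i \lambda^\top f(x_i)
+ \log\frac1B \sum_j e^{\lambda^\top f(b_j)}
+ \frac{\beta}{\sqrt m} \sum_k s_k |\lambda_k|,
$$

where $s_k$ is the feature's standard deviation over the background.
Suitability is the Gibbs intensity $e^{\lambda^\top f(x)}$ rescaled by its
maximum over valid in-range cells to $[0, 1]$. Every downstream product
(omission threshold, partial ROC, normalized D/I surfaces) is invariant to
monotone rescaling, so no logistic transform is applied.

Design choices worth spelling out:

* **Feature classes.** Linear + quadratic by default, optional pairwise
  products. The predictors are already smooth principal components, so
  quadratic features span unimodal Gaussian-like responses; hinge and
  threshold features are omitted, keeping the objective strictly convex and
  the fit reproducible.
* **Penalty scaling.** The L1 penalty is $\beta s_k/\sqrt m$ per feature
  (default $\beta = 1$). The $1/\sqrt m$ factor matches the sampling scale of
  the presence feature means: under a no-signal null the gradient at zero has
  magnitude $\approx s_k/\sqrt m$, so the penalty suppresses noise features
  at every sample size while letting genuine responses through. A flat
  penalty of $\beta \sum_k s_k|\lambda_k|$ with $\beta = 1$ would exceed the
  presence-background mean shifts of realistic niches and drive the entire
  weight vector to exactly zero.
* **Optimizer.** Proximal Newton: at each step the smooth part is expanded to
  second order (the Hessian is the background feature covariance under the
  current Gibbs weights) and the L1-penalized quadratic subproblem is solved
  by coordinate descent with soft thresholding, followed by an Armijo line
  search on the true objective. Convergence is declared at a KKT residual of
  `1e-6`; typical fits converge in well under 20 outer iterations.
  Degenerate all-zero solutions (very large `beta`) are detected exactly at
  the first KKT check.
* **No extrapolation.** Training min/max per predictor are recorded; at
  prediction time any cell with a predictor outside that rectangle receives
  suitability 0 and a novelty flag. Values are never clamped into range.
* **Replicates.** Each of the 10 bootstrap replicates draws
  $\lceil 0.5\,n \rceil$ calibration points with replacement (a distinct
  deterministic sub-seed per replicate) against one shared background sample,
  so the per-cell replicate range isolates occurrence-sampling uncertainty.
  The per-cell median is the point estimate.

# The virtual world

`make_environment()` builds `n_layers = 15` climate-like layers as a fixed
random linear mixture of `n_latent = 2` smooth latent gradients
(kernel-smoothed white noise, standardized) plus independent cell noise
(`noise_sd = 0.05`). This emulates what matters statistically about a
bioclimatic stack: strong mutual correlation, low effective rank, and
spatial autocorrelation (`smooth_sigma = 6` cells). It does not attempt to
mimic real marginal distributions, units, or physical relationships between
temperature and precipitation summaries — so passing tests certify the
statistical machinery, not fidelity to any real climate.

Species truth is an axis-aligned Gaussian in latent space
(`true_niche()`): smooth, unimodal, and recoverable by quadratic features.
The default widths are isotropic (1 latent standard deviation), the natural
neutral choice in standardized latent coordinates. The default pair of
species (niche centers `(0.5, 0.3)` and `(-0.2, 0.6)`) overlaps broadly, the
configuration under which the background-similarity test should fail to
reject.

Occurrence sampling draws cells with probability proportional to true
suitability (the presence-background estimand), places points uniformly
within cells, then contaminates the sample the way real compilations are
contaminated: 30% exact duplicates appended and 25% of records rounded to
one decimal place and flagged low-precision. These rates echo, at desk
scale, the heavy duplication and precision loss of published vector
compilations; the cleaning cascade must remove exactly these contaminants,
and the generator's bookkeeping makes that checkable.

Future climates: each RCP gets a shift magnitude (0.25, 0.5, 0.75, 1.25
latent standard deviations for RCP 2.6/4.5/6.0/8.5) applied along one fixed
random unit vector in latent space, scaled by a period multiplier (1.0 for
2050, 1.5 for 2070), plus a GCM-specific smooth perturbation field
(`pert_sd = 0.15`, one deterministic sub-seed per GCM, shared by that GCM
across scenarios). The magnitudes are strictly increasing with scenario
intensity — the single property downstream monotonicity checks rely on; the
absolute values are otherwise a free choice of the generator. 9 GCMs x 4
RCPs x 2 periods yields the standard 72 future stacks.

# Numerical and procedural choices

* **Grid convention.** North-up square cells; a cell owns its western and
  top edges (half-open boxes), so point-to-cell assignment is a total
  function and thinning/extraction are deterministic. Area is counted in
  cells; area-change percentages are reported against both the present
  suitable area and the total valid area, since the two conventions differ
  and both are in circulation.
* **Raster format.** Rasters are read and written as ESRI ASCII grids —
  the plain-text raster format long native to maximum-entropy SDM tooling —
  with values at full double precision (`%.17g`), which makes write/read
  round-trips value-exact and pipeline outputs diffable.
* **PCA.** Correlation-matrix PCA (layers z-scored first): bioclimatic
  variables have incommensurate units, and covariance PCA would be dominated
  by precipitation-scale layers. Fitted on all non-nodata cells of the
  present-day stack; future stacks are centered, scaled and projected with
  the *present-day* statistics and loadings only. Loading signs are fixed
  (largest-magnitude entry positive) for backend-independent
  reproducibility. Default 8 components retained.
* **Thresholding.** `tau` is the largest calibration-point suitability value
  whose strict-omission fraction stays within `E = 0.05`; the binary rule is
  `>= tau`. Maximality is brute-force verified in the tests.
* **Partial ROC.** 100 equal-width cutoffs on [0, 1]; the curve is
  restricted to sensitivity `>= 1 - E` with the boundary crossing linearly
  interpolated, which makes the degenerate constant-map case come out at
  ratio exactly 1. The p-value is the fraction of bootstrap iterations with
  ratio at most 1 (counted with a `1e-12` guard so the degenerate ratio-1
  case is classified as non-significant).
* **Overlap.** D and I are computed on surfaces normalized over the shared
  valid mask of the two predictions; the 5th percentile of the null uses
  linear interpolation of order statistics; the test is one-tailed (only low
  similarity rejects). Null replicates reuse the real fits' background and
  predictor stack, isolating the randomization to the occurrence points.
* **Seeds.** Every stochastic stage takes an explicit seed; internal
  sub-seeds derive deterministically from the master seed (and stay below
  2^31), so a pipeline run is bit-reproducible from `(config, seed)`.

# Problem sizes used in validation

The test-suite and acceptance runs use the default 100 x 120 world for
statistical checks (niche recovery with a 400-point calibration set and
10,000 background cells; partial-ROC calibration at 200-500 iterations;
background-similarity discrimination over 20 seeds at 50 replicates) and a
50 x 60 grid with the full 72-stack scenario design for the end-to-end
determinism check. These sizes were chosen so each property is measured with
comfortable statistical margin while a full validation pass stays a
desk-scale computation.

# Known limitations

* The virtual world's two latent gradients make PCA trivially successful;
  real bioclimatic stacks have higher effective rank, and 8 components is a
  convention inherited from that setting, not a universal constant
  (`select_components()` exists for principled choices).
* The maximum-entropy core is the estimand of MaxEnt's raw output, not a
  port of any MaxEnt release: hinge/threshold features, the logistic
  transform, and `.lambdas` compatibility are deliberately absent.
* Low-precision detection on flag-less CSVs uses a one-decimal-place proxy,
  which cannot distinguish a genuinely coarse record from a point that
  happens to sit on a tenth-degree line.
* Areas are cell counts, not km^2; at a fixed grid this leaves all ratios
  unchanged but absolute areas are latitude-weighted in reality.
* The background-similarity decision is the percentile-rule boolean; the
  empirical percentile rank is reported as an auxiliary quantity, not as a
  calibrated p-value.
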