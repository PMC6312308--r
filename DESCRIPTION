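Package: nichecast
Title: Ecological Niche Modeling and Climate-Change Projection for Disease Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-background ecological niche modeling with a maximum-entropy
    (Gibbs) model core, built as a complete, testable pipeline: occurrence
    cleaning (precision filtering, exact deduplication, one-record-per-pixel
    thinning, random calibration/evaluation splits), correlation-matrix PCA of
    bioclimatic-style environmental stacks with projection of future climate
    scenarios through present-day loadings, bootstrapped model replicates with
    median and uncertainty-range summaries, omission-rate thresholding, GCM
    ensemble medians, agreement/stability maps and area-change accounting,
    partial-ROC and cumulative binomial validation, and niche-overlap statistics
    (Schoener's D, Hellinger-derived I) with the background-similarity
    randomization test. Includes a synthetic virtual-species world generator
    with known true suitability so the whole pipeline can be exercised and
    validated end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
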