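Package: gaitdiff
Title: Silhouette-Difference Gait Recognition with Average Gait
    Differential Images and 2DPCA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end silhouette-based human gait recognition. Builds
    motion templates from binary silhouette sequences: the average gait
    differential image (AGDI), the per-pixel mean of XOR differences
    between adjacent aligned silhouettes, and the gait energy image (GEI)
    baseline. Extracts features with two-dimensional principal component
    analysis (2DPCA) operating directly on template matrices through the
    n x n image covariance matrix, with a vectorized-PCA baseline for
    comparison. Evaluates identification (nearest-neighbour matching,
    cumulative match characteristic curves) and verification (z-normed
    similarities, FAR/FRR/EER). Includes silhouette preprocessing
    (Gaussian background subtraction, height normalization, centroid
    alignment) and a deterministic parametric walking-silhouette
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
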