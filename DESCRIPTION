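Package: actiph
Title: Windowed Persistent Homology for Actigraphy Signal Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Computes zero-dimensional sublevel-set persistence diagrams of
    discrete time series through an explicit extrema-ordering and pairing
    algorithm, segments long signals into fixed-length rectangular windows,
    and compares signals window by window using a modified Hausdorff
    semimetric, the Hausdorff distance, or q-Wasserstein distances between
    persistence diagrams.  Includes cohort-level tooling for wearable
    activity-count studies: outcome labelling from weight trajectories,
    pairwise failure/success group analysis, unpaired t tests, a
    random-label control, baseline signal features (power, entropy, mean,
    Pearson correlation), CSV readers for minute-level accelerometer
    tables, and a synthetic actigraphy cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
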