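Package: ddetector
Title: Discontinuity Detection in Rank-Ordered Census Data
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Locates discontinuities (significant gaps) in rank-ordered
    census data such as community body-mass distributions. A unimodal
    "neutral null" is built as the Gaussian kernel density estimate with
    the smallest bandwidth that is still unimodal on log10-transformed
    data; observed rank gaps are then compared against gap distributions
    obtained by resampling that null, and gaps exceeding a chosen
    percentile are flagged as discontinuities. Includes the classic
    difference-index baselines (Holling index, Siemann-Brown index), a
    Gaussian-mixture census simulator with known gap locations, and a
    simulation-based sensitivity analysis over sample size and census
    success with BIC-selected mixture clustering of detected gap
    locations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
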