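Package: vegsense
Title: Vegetation Trend Analysis, REOF Regionalization, and Climate
    Sensitivity Indexing for Gridded NDVI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing vegetation change and its sensitivity to
    climate variability on regular latitude-longitude grids. Implements
    growing-season NDVI preprocessing (maximum value compositing,
    growing-season subsetting, bare-ground masking, bilinear regridding of
    climate fields), per-pixel trend detection with ordinary least squares,
    Theil-Sen slopes and the Mann-Kendall test with a five-class change
    categorization, hybrid regionalization of vegetation anomalies by
    rotated empirical orthogonal functions (North's Rule of Thumb
    retention, Varimax rotation, loading-maxima-seeded K-means, geographic
    merge/split), and a Seddon-style Vegetation Sensitivity Index with
    per-pixel climate weights, variance-percentile sensitivities,
    contributions and dominant-driver maps. Includes a synthetic gridded
    data generator with planted regional structure, trends and
    NDVI-climate couplings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
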