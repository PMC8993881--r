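Package: catscape
Title: Population-Level Utilization Distributions for GPS-Tracked Domestic Cats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for turning high-throughput GPS telemetry of free-ranging
    pet cats into individual and population-level utilization distributions.
    Implements the standard pre-processing filters for collar data (elevation,
    settling-in days, download days, horizontal position error, thinning),
    sequential position-cluster detection for excising indoor activity at the
    owner's residence, Brownian bridge movement model (BBMM) estimation of
    motion variance and utilization-distribution rasters, volume-contour home
    ranges, and the aggregation of individual utilization distributions --
    weighted by each cat's average daily outdoor tracking fraction -- into a
    population-level intensity surface (a "catscape"), together with spatial
    summary statistics and a synthetic cat-population generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
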