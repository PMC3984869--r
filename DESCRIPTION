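Package: ttclust
Title: Two-Step Time Series Clustering with Affinity Subclusters and DTW Merging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Shape-based clustering of equal-length time series in two steps.
    Series are first grouped into fine-grained subclusters by an affinity
    search (CAST) over a Euclidean similarity matrix, each subcluster is
    summarised by an affinity-weighted prototype, and the prototypes are then
    partitioned with k-medoids on their dynamic time warping (DTW) distances.
    Includes a seeded Cylinder-Bell-Funnel benchmark generator, piecewise
    aggregate approximation, conventional k-medoids baselines, and external
    validation statistics (Rand index, normalized entropy, conditional
    entropy, reduction factor, majority-class error rate).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
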