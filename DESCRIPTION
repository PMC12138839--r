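Package: warpnet
Title: Dynamic Time Warp Symptom Networks for Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds symptom networks from short panel time series using
    dynamic time warping (DTW). Attribute trajectories are valence-aligned,
    centered within person and standardized at the group level; pairwise DTW
    distances (Sakoe-Chiba band, symmetric2 step pattern) are aggregated
    across subjects and imputation replicates into an undirected
    co-occurrence network with hierarchically clustered dimensions; a
    forward-only lag-1 directed DTW yields lead-lag contrasts, significance
    tests for directed edges, and standardized out-/in-strength centralities
    with confidence intervals. Includes a synthetic panel generator with
    planted cluster and lead-lag structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
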