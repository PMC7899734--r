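Package: gazenet
Title: Dynamic Network Analysis of Eye-Movement Scanpaths over Moving Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing eye-movement scanpaths recorded over moving,
    overlapping, multi-element targets such as aircraft on a radar display.
    Fixations are resolved against time-varying areas of interest (AOIs),
    collapsed into per-interval AOI fixation sequences, and transformed into a
    dynamic network: one weighted directed transition network per time
    interval. Time-resolved target importance is quantified by indegree,
    closeness, and betweenness over an inverse-transition-count distance, with
    percent and distance normalization for comparison across intervals and
    observers. Includes deterministic mental-map-preserving grid layouts with
    small-multiple network, dot-plot, and bar-plot visualizations, plus a
    synthetic scenario generator (moving targets and Markov-governed
    scanpaths) for end-to-end testing without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cli,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    scales,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
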