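Package: cortexline
Title: Virtual-Line ROI Profiling of Adjacent Category-Selective Cortical Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to profile category selectivity and invariance along a
    virtual line of regions of interest connecting two adjacent
    category-selective patches (such as the fusiform face area and the
    parahippocampal place area) on a triangulated cortical surface.
    Includes a synthetic-cortex generator based on divisive normalization,
    block-design GLM beta estimation, equally spaced line-ROI construction
    with geodesic distances, selectivity and slope statistics with
    repeated-measures ANOVAs, cross-condition multivariate pattern
    classification, and a surface searchlight decoder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    yaml,
    readr,
    e1071,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
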