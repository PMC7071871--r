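Package: pigmentr
Title: Topological Quantification of Self-Organized Pigment-Cell Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated, interpretable quantification of spot and stripe
    patterns from agent (pigment-cell) coordinate data. Combines
    Vietoris-Rips persistent homology on a horizontally periodic (cylinder)
    metric with single-linkage clustering and principal component analysis
    to count stripes, interstripes and spots, flag pattern breaks, measure
    maximum band widths, stripe curviness, spot size, roundness, spacing
    regularity and centre width, and detect stripe-formation events from
    developmental snapshot series. Includes a seeded generator of
    ground-truthed synthetic point patterns (bands, spots, breaks,
    undulation, figure-eights, snapshot series) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
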