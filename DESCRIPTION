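Package: apvenn
Title: Accurate Area-Proportional 3-Venn Diagrams with Ellipses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Draws area-proportional Venn diagrams for three sets using
    ellipses, so that the area of each of the seven interior regions is
    directly proportional to a supplied positive quantity. Region areas of
    three overlapping ellipses are computed analytically from the conic
    intersection points by arc-segment (Green's theorem) integration. A
    deterministic hill-climbing optimizer with a halving cooling schedule
    and a rerun escape minimises a ratio-penalised least-squares cost,
    starting from a rational three-circle layout built by lens-area
    bisection. Includes a diagram goodness measure (diagError), a
    venneuler-style stress metric, synthetic data generators for drawable
    and uniform-random quantities, an evaluation harness, SVG/PNG/text
    export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
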