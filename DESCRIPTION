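Package: pulseroi
Title: Scribble-Seeded Graph-Cut Scoring of Pulsating Regions in Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the contraction behaviour of a pulsating region of
    interest (such as the boar scrotum during semen collection) from video
    frames. Provides scribble-seeded binary graph-cut segmentation with a
    histogram data term solved exactly by min-cut/max-flow, binary mask
    refinement (fill holes, clear borders, erode), region-size (pixel
    fraction) time series with prominence-based extrema detection,
    contraction intensity and frequency statistics, and a linear
    mixed-effects correlation screen (random intercept and uncorrelated
    random slope, grouped by animal) against semen-quality variables.
    Includes a synthetic phantom video generator and a grouped
    semen-variable simulator with analytically known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    lme4,
    png,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    igraph,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
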