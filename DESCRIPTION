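Package: visdemand
Title: Quantifying Everyday Visual Demands from Egocentric Scene Snapshots
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the visual demands of everyday scenes
    captured with head-mounted cameras, aimed at low-vision research. Loads
    PNG/TIFF snapshot frames, linearizes sRGB and converts to 16-bit linear
    luminance, and computes per-image metrics: percentile-tail contrast,
    normalized global entropy, textured-area fraction from a 9x9 local
    entropy filter, high-spatial-frequency area from a 3x3 range filter, and
    Sobel edge-area fraction. Converts annotated object pixel spans to
    degrees of visual angle and logMAR, validates 14-classifier scene codes
    against a shipped schema, maps narrated tasks to a 48-item visual
    functioning questionnaire vocabulary, computes inter-rater percent
    agreement, and produces dual task rankings, classifier distributions and
    word frequencies. A synthetic-data module generates images and coding
    tables with analytically known ground truth so the whole pipeline is
    testable without study recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
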