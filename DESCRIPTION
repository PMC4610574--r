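Package: inflocount
Title: Counting Grapevine Flowers in Inflorescence Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and counts grapevine flowers in photographs of a single
    inflorescence taken against a dark background. Flowers are quasi-spherical
    and each produces a point of maximum light reflection, so candidates are
    found as connected components that are regional maxima in the CIE 1976 L*
    lightness channel inside a colour-segmented region of interest, then
    screened by two statistical post-filters (a robust size fence and a
    moment-ellipse elongation filter). Includes a seeded synthetic-scene
    generator with ground-truth flower centres, a point-matching
    precision/recall evaluation protocol with the redundant-detection rule,
    and command-line entry points for detection, evaluation and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    grDevices,
    stats,
    tools,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
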