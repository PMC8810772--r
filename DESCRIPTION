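Package: wormrig
Title: Simulated Dual-Resolution Tracking and Motility Analysis of C. elegans on Petri Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully simulated Cartesian-robot rig for dual-resolution
    monitoring of Caenorhabditis elegans on standard 55 mm Petri plates.
    Provides a scene simulator (per-strain persistent-random-walk motility
    models rendered as backlit macro and micro image sequences), closed-loop
    active-vision backlight control, adaptive-threshold multi-worm software
    tracking with optimal identity association and censoring, a virtual
    XY/Z robot with pixel-to-step visual servoing and autofocus, a
    state-machine tracking controller with scheduled high-resolution
    capture, and displacement-module motility metrics with nonparametric
    rank-sum strain comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    clue,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
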