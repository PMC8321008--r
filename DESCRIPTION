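Package: mealscan
Title: Food-Intake Action Detection from Top-View Depth Video
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and counts food-intake actions of a person seated at a
    table, from sequences of top-down depth frames (ceiling-mounted Kinect-v1
    style sensor). Implements depth preprocessing (hole filling, background
    subtraction, median denoising, Sobel edges), point-cloud extraction via
    pinhole intrinsics, an adaptive 50-node self-organizing-map skeleton
    tracker with joint-fusion detection and reset, an automatic start/end of
    meal state machine based on head-height history and hands-on-table checks,
    dwell-based intake-action counting, and an MAE/MRE evaluation harness.
    Ships a seeded synthetic top-view depth scene generator with known ground
    truth so the whole pipeline is testable without sensor hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
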