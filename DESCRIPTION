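Package: pitchspace
Title: Possession-Level Spatiotemporal Analysis of Football Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts possession-level spatiotemporal features from 2-D
    player and ball tracking data in association football: ball path
    metrics (distance, speed, coefficient of variation, approximate
    entropy, length/width ratio), team and game space metrics (convex-hull
    effective playing space, game length and width), and end-of-possession
    metrics (deepest location, offensive available space, opponents in
    that space). Provides possession segmentation with duration and
    set-piece inclusion criteria, two-group statistics (Welch t-tests,
    standardized differences, magnitude-based inference with probabilistic
    labels), correlation-matrix PCA with varimax rotation together with
    Bartlett sphericity and Kaiser-Meyer-Olkin adequacy checks, and a
    seeded synthetic match generator with ground-truth sidecars so the
    whole pipeline can be exercised without proprietary tracking feeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
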