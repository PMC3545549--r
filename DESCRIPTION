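Package: swimvel
Title: Front-Crawl Swimming Velocity from a Single Inertial Measurement Unit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates instantaneous and per-stroke-cycle front-crawl swimming
    velocity from a single sacrum-worn inertial measurement unit (3D
    accelerometer + 3D gyroscope). Orientation is tracked by quaternion
    strapdown integration of the gyroscope and corrected per stroke cycle using
    the biomechanical constraint that the sacrum rolls on average about the
    swimming direction. Forward acceleration in the pool frame is integrated to
    velocity, and integration drift is removed by segmenting the acceleration
    with a geometric-moving-average change detector, fitting shape-preserving
    splines to per-cycle velocity extrema, subtracting the envelope midline and
    anchoring to the known trial mean velocity. Includes a tethered-speedometer
    reference model with parallax correction, method-agreement statistics
    (Bland-Altman limits of agreement, normalized pairwise variability index,
    intra-cyclic velocity variation, Spearman correlation, instantaneous error
    measures), and a synthetic swimmer/sensor simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
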