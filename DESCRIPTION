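Package: neargaze
Title: Gaze Tracking for Near-Eye Infrared Camera Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete, testable gaze-tracking pipeline for head-mounted
    eye trackers that pair a near-eye display with an infrared eye camera.
    Provides a synthetic renderer for annotated dark-pupil eye frames
    (corneal glints, eyelid blinks, nystagmus jitter), pupil-center
    detection by robust consensus ellipse fitting, nine-mark calibration
    with outlier-rejected mean pupil centers, a second-order polynomial
    mapping from pupil centers to display coordinates, coarse gaze-zone
    and blink classification, and angular-accuracy evaluation in degrees
    of visual angle. Includes a command-line interface for reproducible
    simulate/calibrate/track/evaluate runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    optparse,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
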