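Package: optomotr
Title: Simulation and Analysis of Tethered-Fly Optomotor Experiments on a Virtual-Reality Treadmill
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A headless, fully testable re-implementation of an inexpensive
    spherical-treadmill virtual-reality stack for walking Drosophila:
    view-angle-corrected rendering of cylinder-projected grating and bar
    stimuli on a flat display, open- and closed-loop trial scheduling with
    frame and round-trip latency accounting under an injectable simulated
    transport, FicTrac-format treadmill-data input/output with conversion to
    physical units, a synthetic walking fly with a temporal-frequency-tuned
    optomotor response, and the turning-response analysis chain producing
    temporal-frequency and spatial-period tuning curves and bar-following
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    signal,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    tidyr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
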