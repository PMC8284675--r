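Package: crowdga
Title: Genetic-Algorithm Analysis of Visual Crowding in Dense Displays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tilt-discrimination observers (linear pooling under
    Bouma's law, a population-code decoder, and a two-stage grouping model)
    on dense 15x19 bar displays, evolves the displays with a genetic
    algorithm to maximise observer accuracy, and quantifies which flanker
    locations drive the improvement with significance maps against a
    neutral (random-selection) control. Includes the sparse-display
    (Bouma's law) and vertical-proportion measures, noise calibration to a
    target accuracy, and reporting and plotting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    tibble,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
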