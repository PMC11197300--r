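Package: bloomwatch
Title: Citizen-Science Phenology Cleaning and Kinetic Bloom-Date Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning opportunistic citizen-science records of fruit
    tree flowering into calibrated bloom-date models. Provides quality-control
    filters for submitted phenology records (photo checks, media-spike dates,
    interquartile-range outlier removal), aggregation onto a 0.1 degree
    temperature grid, downscaling of daily minimum/maximum temperatures to
    idealized hourly series, a kinetic chill/heat bloom model (dynamic-model
    chill portions followed by weighted growing degree hours), bounded
    simulated-annealing calibration with iterative refinement and residual
    bootstrap uncertainty, per-cultivar latitudinal trend tests with
    false-discovery-rate control, and spatial prediction of flowering onset
    with Jenks natural-breaks classification. A seeded synthetic-data
    generator emulates gridded British spring temperatures and noisy
    submissions so the full pipeline can be exercised offline with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
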