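Package: cardiofunc
Title: Quantitative Image Analysis for Micropatterned Cardiac Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for functional imaging of engineered cardiac
    tissue on micropatterned substrates. Implements subset-based digital image
    correlation of bright-field contraction videos, strain-tensor and
    principal-strain fields with masked contractile-strain summaries,
    calcium-transient optical-mapping metrics (activation maps, duration at
    80% relaxation, rise-up time, conduction velocity and its anisotropy),
    windowed-FFT orientation analysis of fiber and myofibril images,
    area-coverage statistics, and cell-migration trajectory statistics.
    Ships synthetic generators with analytic ground truth for every
    modality so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
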