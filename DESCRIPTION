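Package: edgeforce
Title: Cell-Edge Morphodynamics, Traction Force Cytometry and
    Event-Aligned Signaling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies local cell-membrane protrusion and retraction
    dynamics together with Rho-GTPase biosensor activity and substrate
    traction forces. Provides FRET ratio computation and drift
    registration for time-lapse stacks, bead-image particle image
    velocimetry and regularized Fourier-transform traction cytometry,
    1-um edge-sector by depth-window sampling with edge-velocity
    extraction, protrusion/retraction event detection with distance and
    duration filters, event-aligned ensemble averaging with bootstrap
    confidence intervals, lagged cross-correlation of signaling and
    force time series, difference-in-difference quantification of
    optogenetic perturbations, and a resampling-based false discovery
    rate procedure. Includes a seeded synthetic-data generator with
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    readr,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
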