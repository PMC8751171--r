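Package: mslur
Title: Multiscale Land Use Regression for Intraurban PM2.5 Exposure Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage multiscale land use regression (LUR) modelling of
    intraurban fine particulate matter (PM2.5). The city scale couples
    satellite aerosol optical depth (AOD), kriged station meteorology and
    circular-buffer land-use, road-network and building-morphology predictors
    in a geographically and temporally weighted regression (GTWR) with
    AICc-based bandwidth selection and leave-one-out cross-validation. The
    neighbourhood scale models street-level deviations (delta PM2.5) from
    RH-corrected, background-adjusted mobile sampling using sky view factor,
    point-based frontal area index, and road-segment centrality and space
    syntax metrics, with a no-extrapolation validity mask. A seeded synthetic
    city generator provides a fully reproducible test bed, and mapping tools
    combine the seasonal surfaces and the road-space delta layer into a final
    exposure map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
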