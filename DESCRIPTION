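Package: autoflux
Title: Two-Step Analysis of Autophagosome Formation and Degradation from
    LC3-II Turnover Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts four-condition LC3-II Western-blot measurements
    (control/stimulus crossed with presence/absence of a lysosomal
    inhibitor such as bafilomycin) into per-replicate estimates of
    autophagosome formation, degradation, steady-state pool size, and net
    turnover, using a two-step input-output pool model of autophagy. The
    main entry point flux_fit() returns a classed model object with
    print, summary, coef, residuals, plot, and simulate methods. Also
    provides a lane-profile gel densitometry routine (baseline
    subtraction and peak integration) with a synthetic blot-image
    generator, a forward scenario simulator for validation and power
    exploration, and the factorial ANOVA / one-tailed t-test /
    Holm-Sidak statistical decision pipeline used to interpret the
    estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
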