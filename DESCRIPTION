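Package: rcaim
Title: Reduced-Complexity Steady-State Modelling of PM2.5 Changes from
    Emission Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reduced-complexity, annual-average air quality model for
    estimating changes in primary and secondary fine particulate matter
    (PM2.5) concentrations caused by marginal changes in emissions of five
    precursor species (VOC, NOx, NH3, SOx, primary PM2.5).  The model
    solves a discretized steady-state reaction-advection-diffusion system
    on a variable-resolution (quadtree-style) grid using pre-averaged
    meteorological and chemical fields: upwind mean advection, symmetric
    deviation advection, combined local-nonlocal boundary-layer mixing,
    first-order sulfur oxidation, instantaneous marginal gas/particle
    partitioning, and dry/wet deposition.  Includes a synthetic
    annual-average field generator, emission-scenario ingestion from
    GeoJSON with Briggs plume rise, population-weighted exposure
    summaries, and standard model-evaluation statistics (MB, ME, MFB,
    MFE, MR, regression slope/intercept/R-squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
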