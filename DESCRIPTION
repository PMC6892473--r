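Package: firePM
Title: Wildland-Fire Smoke PM2.5 Exposure Assessment from Paired
    Chemical-Transport-Model Runs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Attributes fine particulate matter (PM2.5) to wildland-fire
    smoke by differencing paired gridded chemical-transport-model runs
    (all emission sources versus no-fire), aggregates daily fields to
    administrative units under the cell-centroid rule, classifies units
    into quartile-based annual exposure classes, detects multi-day
    exceedance episodes ("smokewaves") against the 35 ug/m3 24-h NAAQS
    level, tabulates populations and health-event counts at risk by
    exposure class, and evaluates gridded predictions of PM2.5 carbon
    against monitor observations stratified by predicted fire impact.
    Includes a seeded synthetic-scenario generator (smooth positive
    background plus advected Gaussian fire plumes, unit polygons,
    population tables and noisy monitor records) so the whole pipeline
    is testable at desk scale without external model output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
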