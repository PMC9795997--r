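Package: needleiso
Title: Dynamic Modelling of Needle Sugar and Water-Soluble Carbohydrate
    Oxygen-18 and Carbon-13 Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A leaf-level process model of the formation of delta-18O and
    delta-13C in conifer needle sugars and bulk water-soluble carbohydrates
    (WSC), driven by half-hourly meteorology. Couples a Farquhar-type shoot
    gas exchange solver (with mesophyll conductance and soil-moisture
    limitation) to Craig-Gordon, two-pool and Peclet leaf-water 18O
    enrichment models (steady and non-steady state), a 13C discrimination
    model of net CO2 exchange valid day and night, and an isotope mass
    balance of a well-mixed needle sugar pool diluted by pinitol to bulk
    WSC. Includes a signal-formation-period weighting analysis, a synthetic
    boreal growing-season driver generator, a daily source-water bucket
    model, and evaluation utilities (midday sampling windows, fit metrics,
    model-variant grids and environmental-signal correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite
Config/testthat/edition: 3
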