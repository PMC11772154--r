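Package: peatcausal
Title: Causal Analysis of Peatland Carbon-Water Flux Time Series
Version: 0.1.0
Authors@R:
    person("Peat", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how atmospheric drying and soil moisture
    jointly control photosynthesis in peatlands from weekly eddy-covariance
    records. Derives potential evapotranspiration (Penman), bulk surface
    conductance (inverted Penman-Monteith), aerodynamic conductances and
    evaporative fraction from flux-tower data; computes drought indicators
    (moisture coefficient, a log-logistic SPEI) and annual high/low stress
    classifications; implements empirical dynamic modelling from first
    principles (time-delay embedding, simplex projection, S-map interaction
    strengths, convergent cross mapping with analytic standard errors);
    and attributes gross primary productivity variability through lagged
    cross-correlation, segmented threshold regression, and redundancy
    analysis. Ships a seeded synthetic bog generator with known causal
    structure so the whole pipeline is testable without tower data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
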