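Package: vulnindex
Title: Composite Vulnerability Indices and Equity in Health-Service
    Availability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs HDI-style composite vulnerability indices over
    administrative districts (min-max normalization with explicit indicator
    orientation, equal weighting, ranking, tertile or general quantile-group
    assignment), computes health-insurance-scheme availability and
    utilization indicators per 100,000 enrolled persons, quantifies
    between-group inequality with rate ratios and rate differences, tests
    association between vulnerability and availability with Pearson
    correlations (t-test p-values, Fisher-z confidence intervals), and
    exports choropleth-ready GeoJSON layers. Ships the printed district and
    tertile tables of a published analysis of Chhattisgarh's universal
    hospital-insurance scheme as fixtures, and a seeded synthetic
    district-panel generator with a centre-periphery vulnerability gradient
    for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
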