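Package: phosmarker
Title: Integrative Phosphoproteome and Drug-Response Marker Analysis
Version: 0.1.0
Authors@R:
    person("phosmarker", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for integrative analysis of baseline (phospho)proteomes of
    cancer cell line panels against phenotypic drug-sensitivity data: summation
    of phosphopeptide intensities to phosphoproteins, pathway and kinase
    relative-activity landscapes, weighted correlation-network module detection
    with topological overlap and guilt-by-association annotation transfer,
    single-cell-line outlier marker calling, correlation / elastic-net /
    random-forest drug-association modeling, and sparse multiblock partial
    least squares regression that clusters drugs sharing markers. Includes a
    seeded synthetic-data generator emulating NCI60/CRC65-like panels with
    planted ground truth for every analysis stage, plus a config-driven
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
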