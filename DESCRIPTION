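Package: yearlingr
Title: Yearling Age Structure and Habitat Greenness in Landbird Communities
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the proportion of yearling (second-year)
    adults in landbird communities from constant-effort mist-netting capture
    data. Curates banding records into year-unique individuals, estimates
    age-determination error rates from recapture histories, computes yearling
    proportions at species and community scales, aggregates remote-sensed
    Enhanced Vegetation Index (EVI) grids and in-situ habitat assessments to
    station-scale covariates, and fits a multispecies hierarchical
    Bernoulli/logit model of yearling probability against habitat greenness
    with species-level random intercepts and slopes, treating adults of
    undetermined age as missing outcomes. Includes a synthetic-data generator
    with known ground truth so every stage of the pipeline can be exercised
    and validated by parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    coda,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
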