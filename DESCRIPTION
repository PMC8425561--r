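Package: scentmark
Title: Agent-Based Simulation of Pollinator Foraging with Repellent Scent Marks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spatially explicit agent-based model of pollinators foraging for
    nectar on a continuous toroidal meadow. Flowers refill nectar linearly and
    carry a complementary repellent scent mark that fades as nectar returns;
    pollinators move by a correlated random walk, detect free flowers within a
    fixed radius, and may use the scent mark as an inadvertent social cue to
    reject recently emptied flowers. Includes individual- and community-level
    summary metrics (nectar collected, remaining nectar, visits per flower,
    pollen carryover, with coefficients of variation), factorial experiment
    sweeps over competition, nectar refill and handling cost, and a
    random-sampling global sensitivity analysis ranked by regression-forest
    variable importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
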