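Package: antcrowd
Title: Agent-Based Model of Ant Foraging with Crowding Negative Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit agent-based simulation of mass-recruiting ant
    foraging on a T-maze with two food patches. Foragers recruit nestmates by
    depositing trail pheromone (positive feedback) while a per-patch crowding
    threshold turns away surplus arrivals (negative feedback). The package
    provides the simulation engine, the stable- and changing-environment
    experiment drivers, sensitivity sweeps over colony size, pheromone decay
    rate, maze geometry and dissatisfied-forager routing, summary statistics
    for two-feeder count series (proportions, symmetry index, sustained
    crossing times, bias tests, switch-time regression, Holm adjustment) and
    a synthetic two-feeder count generator with known ground truth for
    testing those statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
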