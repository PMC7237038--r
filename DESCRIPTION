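Package: cyanotaxis
Title: Agent-Based Simulation of Collective Phototaxis in Cyanobacterial Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates colonies of gliding cyanobacteria (such as Synechocystis)
    responding to one or several directional light sources. Cells are overdamped
    self-propelled discs whose headings are biased toward light with a small
    probability per step, interacting through type-IV-pili contact forces with a
    soft-core tanh kernel, and depositing polysaccharide slime on a square lattice
    that lowers the friction later cells experience. Two information-integration
    scenarios for multiple sources (stochastic switching between sources, and
    motion along their vector sum) are implemented, together with the trajectory
    statistics (rose histograms, circular resultants, a von Mises mixture
    classifier) and finger morphometrics that distinguish them, experiment
    presets, and a real-units calibration utility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
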