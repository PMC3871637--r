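Package: pollensel
Title: Pollinator-Mediated Selection from Single-Pollen Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses mixed-array pollination experiments in
    which individual pollen grains deposited on stigmas are genotyped at
    codominant microsatellite loci. Provides grain-level quality control,
    self/outcross classification and likelihood-based (LOD/Delta) paternity
    assignment with simulation-calibrated confidence thresholds, per-flower
    tallies of maternal and paternal pollination success, and hierarchical
    Bayesian Poisson models (crossed random intercepts, MCMC via JAGS) that
    estimate linear and quadratic selection gradients on floral traits and
    classify selection as directional, stabilizing or disruptive from the
    fitness optimum z* = -beta/(2*gamma).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
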