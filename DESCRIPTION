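Package: strataclock
Title: Stratigraphic Calibration of Phylogenies and Relaxed-Clock Divergence
    Dating with Fossil Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconciling the fossil record with molecular-clock
    divergence estimates. Calibrates rooted phylogenies against first
    appearance data to infer ghost lineages and stratigraphic congruence
    metrics (MIG, MSM*, GER); builds node-calibration prior distributions
    (normal midpoint and gamma hard-minimum/soft-maximum rules) from fossil
    age bounds; runs a Bayesian uncorrelated-lognormal relaxed-clock dating
    engine with partitioned GTR+Gamma(+I) likelihoods and a Yule tree prior;
    drives calibration-subset sensitivity designs; and builds fossil- versus
    clock-based lineage-through-time curves. Includes simulators for Yule
    trees, lognormal branch rates, partitioned sequence evolution and binned
    Poisson fossil preservation, plus a South American Land Mammal Age
    (SALMA) time scale and a worked caviomorph-rodent fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
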