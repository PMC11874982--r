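Package: defenseflux
Title: Phylogeny-Aware Association of Prokaryotic Defense Systems with
    Mobile Genetic Element Flux
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how prokaryotic anti-phage/anti-plasmid defense
    systems (restriction-modification, CRISPR-Cas, Abi, CBASS, DRT, Gabija,
    DISARM-like systems) associate with mobile genetic element (MGE)
    abundance and horizontal gene transfer along strain phylogenies.
    Implements per-species Poisson phylogenetic generalized linear mixed
    models with Brownian-motion covariance and conditional AIC model
    comparison; a two-state maximum-likelihood gene gain/loss model with
    discretized-gamma rate categories and per-branch posterior expected
    event counts via uniformization; detection of defense-positive clades
    and their defense-negative sisters with gain/loss-rate log-ratio
    comparisons, depth stratification and d'Agostino skewness tests; and
    branch-level co-gain/co-loss linkage statistics (binomial and Fisher
    exact tests, risk ratios). A fully seeded synthetic-data generator with
    known ground truth (birth-death strain trees, two-state MGE histories,
    linked defense gains, defense-modulated gene-family turnover) supports
    end-to-end calibration and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    lme4,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
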