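Package: overlapMR
Title: Bayesian Mendelian Randomization for One-, Two- and Overlapping-Sample Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariable Mendelian randomization when the instrument-exposure
    and instrument-outcome association studies share none, some or all of their
    participants. A linear structural model with a latent scalar confounder is
    fitted by Markov chain Monte Carlo in which unobserved exposures and
    outcomes of partially overlapping studies are imputed as additional unknown
    quantities (Bayesian data augmentation), so that any overlap pattern
    reduces to a one-sample analysis with missing data. Includes classic
    two-stage least squares and multivariable inverse-variance weighted
    comparators, a synthetic-data generator for overlapping-sample study
    designs, and a simulation harness computing mean, standard deviation,
    coverage and power of the estimated causal effects over replicate
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
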