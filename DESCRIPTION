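Package: spruceABC
Title: Multilocus Population Genetics and Coalescent ABC Inference of
    Spruce Speciation Histories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for inferring the origin and speciation history of
    closely related conifer species from multilocus sequence alignments.
    Provides per-locus diversity statistics (segregating sites, Watterson's
    theta, nucleotide diversity by site class), neutrality tests (Tajima's D,
    Fu and Li's D*, and the maximum-frequency-of-derived-mutation test with
    outgroup polarization), permutation-tested Phi-ST / Hudson F-ST,
    linkage-disequilibrium screening, a structured-coalescent simulator with
    population divergence and migration under the infinite-sites model, and
    likelihood-free inference: partial-least-squares summary-statistic
    reduction, ABC-MCMC sampling, general-linear-model posterior adjustment,
    highest-posterior-density summaries, Bayes-factor model comparison, and a
    stepwise driver for resolving four-species divergence orders with or
    without post-divergence gene flow. A synthetic-data generator produces
    study-shaped datasets with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    MASS,
    mixOmics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
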