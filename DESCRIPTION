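Package: cryptdrift
Title: Stochastic Stem-Cell Competition and Clonal Drift in Intestinal Crypts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and inference tools for neutral and biased drift of
    intestinal stem cells competing in the crypt niche. Implements a
    one-dimensional ring Moran model with an exact birth-death Markov-chain
    oracle, a centre/border niche compartment model of Wnt-ligand inhibition,
    the field's clonal readouts (clone size in eighths, fixation fractions,
    clones per field, partial/full crypt genotype scoring), a three-allele
    Cre-lox recombination model of reporter/genotype discordance, a synthetic
    lineage-tracing cohort generator, and maximum-likelihood estimation of
    stem-cell number and replacement rate from eighths-binned clone sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
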