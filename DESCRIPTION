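Package: gepotts
Title: Bayesian Latent Genetic-Profile Models for Gene-Environment
    Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a flexible Bayesian model for studying gene-environment
    interaction in case-control studies of a candidate region. Multilocus
    genotypes are partitioned into latent risk clusters through a Potts
    prior on a nearest-neighbour genotype graph; cluster-specific logistic
    risk models are fitted by Markov chain Monte Carlo, with the
    intractable Potts normalizing-constant ratio handled by a Monte Carlo
    Metropolis-Hastings update. The number of clusters is selected by the
    deviance information criterion (+1 and +1 standard-error rules), a
    consensus partition is extracted from posterior co-assignment
    proportions by partitioning around medoids, and gene-environment
    interaction is tested by a parametric-bootstrap likelihood-ratio
    procedure. Includes minP-style single-SNP and principal-component
    comparator tests and a case-control simulator with linkage-
    disequilibrium-structured genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
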