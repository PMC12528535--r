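Package: phyloconflict
Title: Gene-Tree Conflict Analysis by Topology Tests, Coalescent
    Simulation, Mixture Classification and Approximate Bayesian
    Computation
Version: 0.1.0
Authors@R:
    person("phyloconflict", "developers", role = c("aut", "cre"),
           email = "maintainers@phyloconflict.invalid")
Description: Tools for dissecting gene-tree/species-tree conflict in small
    species complexes: constrained enumeration of rooted candidate
    topologies, a Felsenstein pruning likelihood kernel with per-site
    log-likelihoods, gene genealogy interrogation via the approximately
    unbiased (AU) topology test with RELL multiscale bootstrapping,
    multispecies-coalescent simulation with admixture (gene trees,
    sequence alignments and stepwise-mutation microsatellite panels),
    exponential-mixture classification of triplet discordance into
    incomplete lineage sorting versus introgression, rejection ABC over
    demographic scenarios with microsatellite summary statistics, and
    Blomberg's K phylogenetic-signal testing. A synthetic-data generator
    produces complete miniature study bundles with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
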