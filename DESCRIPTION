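Package: phyloconflict
Title: Coalescent Simulation, Gene-Tree Conflict Diagnostics, and
    Divergence-Dating Priors for Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing gene-tree/species-tree conflict and for
    preparing relaxed-clock dating analyses in phylogenomic studies.
    Simulates gene trees under the multispecies coalescent from a species
    tree with branch lengths in coalescent units, computes topology-frequency
    spectra and tests whether observed gene-tree discordance is consistent
    with incomplete lineage sorting (topology-frequency correlation),
    computes per-branch normalized quartet supports (q1-q3) and per-node
    gene-tree concordance/conflict classifications, ranks genes by
    clock-likeness (species-tree concordance, root-to-tip variance, tree
    length), constructs fossil-calibration densities (soft-bounded uniform
    and minimum-truncated Cauchy) and gamma rate hyperpriors, and performs
    maximum-likelihood Mk (k-state, one-parameter) ancestral state
    reconstruction. Includes seed-deterministic generators for synthetic
    species trees, error-perturbed gene-tree samples, rate-heterogeneous
    clock fixtures and discrete characters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
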