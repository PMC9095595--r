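Package: elevphylo
Title: Phylogenetic Alpha and Beta Diversity of Communities Along
    Elevational Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community phylogenetics of presence/absence assemblages sampled
    along environmental gradients. Resolves genus-level backbone phylogenies to
    species level under a Yule process to propagate phylogenetic uncertainty,
    selects maximum clade credibility trees, computes Faith's PD, MPD and MNTD
    with standardized effect sizes under independent-swap null models,
    partitions PhyloSor phylogenetic beta diversity into turnover and
    nestedness components (pairwise, adjacent and multiple-site), builds
    climate principal-component predictors, compares candidate regression
    models by BIC, and fits generalized dissimilarity models with monotone
    I-spline transforms, permutation importance and permutation significance.
    Includes a seeded synthetic-data generator (backbone trees, Brownian
    thermal niches, climate gradients, and community assembly under filtering,
    competition or neutral rules) so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    pracma,
    Rcpp,
    splines,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
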