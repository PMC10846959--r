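Package: archolimb
Title: Limb-Bone Morphometrics, Disparity and Locomotor Evolution of
    Early Archosauromorphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for studying locomotor evolution in
    early archosauromorph reptiles from limb-bone data.  Provides 2D
    geometric morphometrics (generalized Procrustes superimposition with
    chord min-d2 semi-landmark sliding and principal component
    ordination), disparity through time (sum of variances with bootstrap
    intervals, bin merging, and permutational MANOVA), quadrupedality and
    cursoriality indices with a phylogenetic ANCOVA under Pagel's lambda,
    fossil-tree time-scaling (minimum branch length and a probabilistic
    birth-death-sampling method), and variable-rates Brownian-motion
    inference by reversible-jump MCMC with stepping-stone marginal
    likelihoods, Bayes-factor grading and a positive-phenotypic-selection
    test.  A synthetic-data module generates limb outlines, measurement
    tables, fossil trees and traits with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    phytools,
    nlme,
    vegan
Config/testthat/edition: 3
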