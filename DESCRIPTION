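Package: hostspec
Title: Host-Use Specificity Analysis for Armored Scale Insect Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing host-use specificity of armored scale
    insects (Hemiptera: Diaspididae) surveyed on individual canopy trees.
    Implements DNA-based species delimitation by genealogical concordance
    across three gene trees with a divergence-threshold rescue for sparse
    species; permutation tests of diet specificity based on Simpson's
    reciprocal diversity index of colonized host trees; a Bayesian
    phylogenetic threshold (liability) model for the binary use or nonuse
    of each host taxon, tested against degree-preserving checkerboard swap
    nulls with Benjamini-Hochberg false-discovery-rate control; and
    Poisson abundance and binomial patch-occupancy generalized linear
    models relating performance to diet breadth, with permutation-based
    significance. A synthetic-data module simulates two-site surveys with
    known ground truth (species partitions, phylogenetic signal, and
    diet-breadth effects) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    seqinr,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
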