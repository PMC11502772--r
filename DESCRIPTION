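Package: traitdims
Title: Dimensionality and Structure of Sparse Functional Trait Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds reduced functional-trait spaces from sparse species-by-trait
    matrices by eigendecomposition of pairwise-complete Pearson correlation
    matrices, quantifies their dimensionality with the effective number of
    dimensions (inverse Simpson diversity of the eigenvalue spectrum) calibrated
    against an uncorrelated-trait null model, and compares trait-relationship
    structure across spaces through angles between trait loading vectors.
    Includes complete-case and Brownian-motion phylogenetically-informed
    principal component analysis variants, and a synthetic-data generator that
    emulates large trait compilations with block-structured trait correlations,
    heterogeneous per-trait completeness and growth-form strata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    vegan,
    phytools,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
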