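Package: cladiv
Title: Clade-Composition Surrogates for Phylogenetic Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phylogeny-free clade indices that track the three dimensions of
    phylogenetic diversity (richness, divergence, regularity) from clade
    proportions and species-richness bookkeeping alone, together with the
    abundance-weighted phylogeny-based metrics they approximate (Faith's PD,
    mean pairwise distance, variance of pairwise distances). Includes a
    simulation workflow that samples species pools from a phylogeny, generates
    random community matrices across species-richness ranges, and quantifies
    surrogate fit accuracy with linear models, generalized least squares with
    an exponential variance function, and nested variance components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    nlme,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
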