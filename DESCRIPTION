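Package: exumet
Title: Community Analysis of Untargeted Root-Exudate Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for presence/absence community analysis of untargeted
    LC-MS root-exudate feature tables from multi-species field designs:
    blank-contaminant and singleton feature filtering, chemical richness
    statistics with Scheffe post hoc letters, a one-vs-rest exact binomial
    species-specificity screen, PCA/RDA/partial-RDA/DCA ordination and
    complete-linkage clustering, Procrustes trait-exudate correlation with
    permutation test, variance partitioning over predictor sets via
    adjusted R-squared inclusion-exclusion, a land-use-intensity index,
    and MS/MS fragment and neutral-loss compound-class annotation. A
    synthetic-data module generates every pipeline input with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
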