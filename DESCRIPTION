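Package: traitplast
Title: Trait Variation and Phenotypic Plasticity in Clonal Common Gardens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of intraspecific trait variation and phenotypic
    plasticity for clonally propagated varieties grown in two contrasting
    common gardens. Provides tree-level trait tables with common/distinct
    variety bookkeeping, derivation of leaf, stem and branch functional
    traits from raw measurements, ANOVA-based partitioning of trait
    variance into genetic, plastic and residual components, the phenotypic
    dissimilarity index (PhD) and the multivariate plasticity index (MVPi),
    per-site varimax-rotated principal component analysis with fast-slow
    strategy scoring, plasticity-strategy correlations, the De Martonne
    aridity index, and a synthetic common-garden data generator with known
    variance components for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    stringi
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
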