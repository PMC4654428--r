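Package: rdsoil
Title: Replant Disease Soil Biotest and Bacterial Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for soil-microbiome biotests of replant
    disease soils: permutation d-tests on Pearson similarity matrices of
    community fingerprints (DGGE lanes), OTU-table transformation,
    taxonomic aggregation, rarefaction and inverse-Simpson diversity,
    Bray-Curtis principal coordinate analysis with one- and two-way ANOSIM,
    a per-taxon treatment-responder screen (ANOVA, Tukey HSD compact
    letters, direction versus control), plant-growth biotest statistics
    (Dunnett many-to-one tests, percent increase, root-to-shoot ratios),
    and a synthetic-data generator that emulates the fingerprints, OTU
    tables, growth tables and qPCR tables the analyses expect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml,
    optparse
Config/testthat/edition: 3
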