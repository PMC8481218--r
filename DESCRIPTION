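Package: collapsescope
Title: Community-Collapse Zonation and Early-Warning Signal Detection in
    Ordered Abundance Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting community collapses in ordered (time- or
    depth-indexed) species-abundance tables, as used in paleoecological and
    paleolimnological records. Provides temporally constrained UPGMA
    clustering for stratigraphic zonation, covariance-based principal
    component ordination, an indicator suite (total abundance, species
    richness, across-taxon standard deviation, rolling-window lag-1
    autoregression, dominant-species relative abundance, taxon ratios),
    loess trend fitting with pointwise confidence bands for small- and
    large-scale signal extraction, pulse/step environmental-event
    classification with an evidence ledger, and a labelled community-collapse
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
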