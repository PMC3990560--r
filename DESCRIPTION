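Package: standcompare
Title: Comparing Forest Structure and Biodiversity Across Heterogeneous Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the structure and biodiversity of managed
    forests surveyed under heterogeneous protocols and environments.
    Computes per-hectare basal area from stratified circular plot
    inventories, stem-based rarefied species richness (median unique
    species in repeated 100-stem draws), annualized change between forest
    revisits, and locally weighted "regional intercomparison" z-scores
    that standardize a forest's metric against inverse-square-distance
    weighted neighbors, using a combined geographic/elevation distance.
    Includes sampling-effort harmonization against 0.1-ha old-growth
    reference transects, major axis (model II) regression with
    permutation tests, one-way ANOVA with Tukey HSD compact letter
    displays for ordinal field ratings, and a synthetic-landscape
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
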