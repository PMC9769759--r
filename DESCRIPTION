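Package: gutmodules
Title: Gut Metabolic Module Scoring and Species-Contribution Analysis for
    Diet-Stratified Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based scoring of Gut Metabolic Modules (GMMs) from
    KEGG-orthologue abundance profiles, pooled and stratified by contributing
    species, with downstream comparison of diet groups: per-species relative
    contributions, a Kruskal-Wallis / Dunn / Benjamini-Hochberg test cascade,
    bootstrap core-microbiota detection, taxon ratios (Firmicutes/Bacteroidetes,
    Prevotella/Bacteroides), Bray-Curtis dissimilarity with principal-coordinates
    ordination, and cross-cohort similarity profiles. Includes readers for
    MetaPhlAn-style taxonomic profiles, HUMAnN-style stratified gene-family
    tables and GMM flat-file definitions, and a synthetic-data generator that
    emulates diet-cohort study designs with planted species-contribution
    effects so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
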