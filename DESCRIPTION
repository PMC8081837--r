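Package: nicheshift
Title: Symbiont-Conferred Range Expansion: Ensemble Niche Models, Field
    Survival and Rhizosphere Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A validated pipeline for projecting how a symbiont-conferred
    physiological gain (increased water-use efficiency) expands a tree
    species' climatically suitable range. Provides ESRI ASCII raster and
    occurrence-point handling with geodesic cell areas; ensemble
    presence/background random-forest distribution models with
    probability-threshold area estimation and a physiological scenario
    transform that rescales precipitation layers; Kaplan-Meier survival
    curves and the Mantel-Haenszel log-rank test implemented from first
    principles; alpha-diversity indexes (Shannon, richness, Simpson
    dominance, Buzas-Gibson evenness, Chao1, ACE), Bray-Curtis
    dissimilarity and principal coordinates analysis for OTU count
    tables; and synthetic-data generators (virtual-species landscapes
    with an analytic suitability surface, interval-censored two-arm
    survival cohorts, multinomial count tables) that supply ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    vegan,
    withr
Config/testthat/edition: 3
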