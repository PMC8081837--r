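#!/usr/bin/env Rscript
# Stage 1 — materialise the synthetic study inputs.
#
# Writes a complete seeded dataset under results/fixtures/: the eight-layer
# virtual bioclim landscape (ESRI ASCII grids), presence/background points
# for the packaged wet-margin species, a 50 + 50 two-arm survival cohort at
# a 3:1 hazard ratio on the field visit schedule, and a three-condition
# rhizosphere count table (5 samples each). Everything downstream reads
# these files, never this script's memory.

suppressPackageStartupMessages(library(nicheshift))

seed <- 1
out <- "results/fixtures"
manifest <- make_fixtures(out, seed = seed)

cat(sprintf("Wrote %d files to %s (seed %d).\n", nrow(manifest), out, seed))
cat("Key files: stack/ (8 layers), points.csv, survival.csv, counts.tsv,\n")
cat("metadata.tsv, true_suitability.asc (the generating surface), config.txt.\n")

# quick orientation: how big is the true suitable range at the 95% rule?
suit <- read_raster(file.path(out, "true_suitability.asc"))
cat(sprintf("True suitable area (suitability >= 0.95): %.0f ha (%.2f%% of cells).\n",
            true_area_ha(suit, 0.95),
            100 * mean(suit$values >= 0.95, na.rm = TRUE)))
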