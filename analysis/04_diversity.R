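#!/usr/bin/env Rscript
# Stage 4 — rhizosphere community structure across the three conditions.
#
# Per-sample alpha-diversity profile (Shannon H, richness S, Simpson
# dominance D, Buzas-Gibson evenness E, Chao1, ACE), Kruskal-Wallis +
# pairwise Mann-Whitney comparisons per index (with the parametric
# ANOVA/Tukey track shown for evenness, mirroring the two-track
# convention), Bartlett's variance check, per-taxon Welch t-tests with
# Bonferroni correction between the inoculated and non-inoculated
# conditions, and a Bray-Curtis PCoA.

suppressPackageStartupMessages(library(nicheshift))

fix <- "results/fixtures"
stopifnot(dir.exists(fix))
dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)

tab <- read_count_table(file.path(fix, "counts.tsv"),
                        file.path(fix, "metadata.tsv"))
prof <- alpha_profile(tab)
write.csv(prof, "results/diversity/alpha_profile.csv", row.names = FALSE)

cat("Group means of the per-sample indexes:\n")
agg <- aggregate(prof[c("H", "S", "D", "E", "chao1", "ace")],
                 by = list(group = prof$group), FUN = mean)
print(agg, digits = 3)

cat("\nKruskal-Wallis across the three conditions (per index):\n")
tests <- lapply(c("H", "S", "D", "E", "chao1", "ace"), function(ix) {
  gt <- compare_groups(prof[[ix]], prof$group, method = "kw_mwu")
  cat(sprintf("  %-6s H = %6.3f, p = %.3f\n", ix, gt$statistic, gt$p))
  gt
})

cat("\nEvenness, parametric track (one-way ANOVA + Tukey HSD):\n")
ev <- compare_groups(prof$E, prof$group, method = "anova_tukey")
cat(sprintf("  F = %.3f on (%d, %d) df, p = %.3f\n",
            ev$statistic, ev$df[1], ev$df[2], ev$p))
bt <- bartlett_test(prof$E, prof$group)
cat(sprintf("  Bartlett variance check: chi2 = %.3f, p = %.3f\n",
            bt$statistic, bt$p))

res <- taxon_ttests(tab, groups = c("Eplus", "Eminus"))
sig <- res[res$p_adjusted < 0.05, ]
cat(sprintf("\nPer-taxon Welch t-tests (E+ vs E-, Bonferroni m = %d): %d significant\n",
            nrow(res), nrow(sig)))
write.csv(res, "results/diversity/taxon_ttests.csv", row.names = FALSE)

ord <- bray_curtis_pcoa(tab)
prop <- ord$ordination$proportion
cat(sprintf("\nBray-Curtis PCoA: axis 1 explains %.1f%%, axis 2 %.1f%% of positive variance\n",
            100 * prop[1], 100 * prop[2]))
coords <- data.frame(sample = rownames(ord$ordination$coordinates),
                     group = unname(tab$groups),
                     ord$ordination$coordinates[, 1:min(3, ncol(ord$ordination$coordinates))])
write.csv(coords, "results/diversity/pcoa_coordinates.csv", row.names = FALSE)
cat("Wrote results/diversity/{alpha_profile.csv, taxon_ttests.csv, pcoa_coordinates.csv}\n")
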