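# nicheshift

Can a root symbiont expand an endangered tree's climatic range? Inoculated
seedlings of a drought-limited Mediterranean tree use water about 15% more
efficiently (WUE = A/E, carbon gain per unit water transpired). `nicheshift`
implements the full computational chain that turns that physiological gain
into a projected range change, plus the two supporting analyses such a field
program produces — a two-arm transplant survival comparison and a
rhizosphere diversity comparison — and validates every stage on synthetic
data with known ground truth.

The pipeline, by stage:

* **Ensemble distribution model.** Presence/background random-forest
  classification on eight bioclim layers (BIO2, BIO4, BIO5, BIO6, BIO12,
  BIO15, BIO18, BIO19): B iterations of a 70/30 train/test split, 500 trees
  each, per-cell presence vote fractions averaged over iterations, and
  suitable area = Σ cell areas over cells with probability ≥ 0.95 (geodesic
  cell areas R²·Δλ·(sin φ₁ − sin φ₂), reported as mean ± SD over iterations
  and as the thresholded ensemble-mean map).
* **Physiological scenario.** The measured WUE gain f (default 14.7%)
  rescales the precipitation layers BIO12 and BIO19 by (1 − f); presences
  are re-extracted from the rescaled layers while background and the
  projection grid stay original, and the expansion ratio is the modified
  over baseline mean area.
* **Survival.** Kaplan–Meier product-limit curves with Greenwood errors and
  the two-group Mantel–Haenszel log-rank test, implemented from first
  principles (χ² = (O₁−E₁)²/ΣV with hypergeometric variances).
* **Diversity.** Per-sample Shannon H (natural log), richness S, Simpson
  dominance D = Σp², Buzas–Gibson evenness e^H/S, bias-corrected Chao1 and
  Chao–Lee ACE; Bray–Curtis dissimilarity with classical PCoA; Kruskal–
  Wallis + Mann–Whitney and ANOVA + Tukey group comparisons; Bartlett
  variance checks; per-taxon Welch t-tests with Bonferroni correction.
* **Synthetic ground truth.** Virtual bioclim landscapes with an analytic
  suitability surface, interval-censored two-arm cohorts on the field visit
  schedule (days 15–733), and multinomial OTU tables with controllable
  evenness — so recovery, calibration and scenario direction can be checked
  against known truth.

See `vignettes/nicheshift-methods.Rmd` for the model details, parameter
choices and known limitations.

## Worked example

The numbered scripts under `analysis/` run the whole study; each is a thin
driver over the package. From the repository root:

```sh
Rscript analysis/01_simulate.R      # write the synthetic study inputs
Rscript analysis/02_niche_model.R   # ensemble SDM + endophyte scenario
Rscript analysis/03_survival.R      # Kaplan-Meier + log-rank
Rscript analysis/04_diversity.R     # alpha diversity, group tests, PCoA
Rscript analysis/05_validation.R    # Monte-Carlo validation studies
```

`02_niche_model.R` prints (seed 1 fixtures, B = 25):

```
Baseline (E-) area:  30418 +/- 6087 ha (mean +/- SD over 25 iterations)
Scenario (E+) area:  46891 +/- 11145 ha
Expansion ratio:     1.54x
Mean test AUC:       1.000 (baseline), 0.990 (scenario)
```

The baseline area is the model's estimate of the virtual species' current
range at the 95% occurrence-probability rule; the scenario area is the same
rule after the learned climate envelope shifts 14.7% toward drier values;
the ratio > 1 is the projected range expansion conferred by the symbiont.
`03_survival.R` prints the per-arm curves and the log-rank comparison:

```
Eminus  final S(733) = 0.00, median survival = 90 days
Eplus   final S(733) = 0.14, median survival = 342 days
Log-rank: chi2 = 37.19, df = 1, p = 1.07e-09
```

— the uninoculated arm reaches 50% mortality at ~3 months, the inoculated
arm at ~11, a difference the Mantel-Haenszel test calls decisively.
`04_diversity.R` prints the per-group index means (the non-inoculated
group is detectably less even by construction: E 0.37 vs 0.63), the
Kruskal-Wallis test per index, the Bartlett variance check and the
variance explained by the first PCoA axes (57.7% + 41.6% here: three
well-separated group centroids).

Equivalently in R, end to end:

```r
library(nicheshift)
make_fixtures("demo", seed = 1)
report <- run_all("demo/config.txt")
report$stages$sdm$expansion_ratio
```

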