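---
title: "Methods: projecting a symbiont-conferred range expansion and validating every stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting a symbiont-conferred range expansion and validating every stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheshift)
```

## The problem

Root endophytes can raise a host tree's water-use efficiency (WUE, the
ratio of photosynthetic carbon gain A to transpiration E). For a
drought-limited endangered tree this is not just physiology: a seedling
that needs ~15% less water can, in principle, persist in places the
uninoculated tree cannot. `nicheshift` implements the computational chain
that turns such a measured WUE gain into a projected change of the
climatically suitable range, together with the two supporting analyses a
field program produces along the way — a two-arm transplant survival
comparison and a rhizosphere community-structure comparison — and, because
the real inputs (global climate rasters, census occurrence points, raw
field records, deposited amplicon data) are not redistributable, a
synthetic-data layer that generates inputs with known ground truth for
every stage.

## The distribution model

The model is a presence/background ensemble classifier. Occurrence points
(presences) and uniformly drawn background points are attributed with the
eight bioclim-role layers (BIO2, BIO4, BIO5, BIO6, BIO12, BIO15, BIO18,
BIO19) by nearest-cell extraction — no interpolation, matching how point
data are usually matched to 30-arc-second climate grids. For each of B
iterations (default B = 100) the labeled points are re-split 70/30 into
train/test, a random forest of 500 classification trees
(floor(sqrt(p)) candidate features per split, unlimited depth) is fitted
on the training split, the test AUC is recorded by the rank-sum
formulation, and the forest's per-cell presence vote fraction is predicted
over the full grid. A cell counts as suitable when its vote fraction is at
or above the threshold p* = 0.95 (inclusive). Two area summaries are
reported, because they answer different questions: the mean ± SD of the
per-iteration thresholded areas (sample SD over B) and the area of the
thresholded ensemble-mean map. Areas are geodesic by default — a
spherical-quadrilateral cell area R²·Δλ·(sin φ_top − sin φ_bottom) per
row, which at 35° S is ~18% below the equatorial value; a `flat_area`
switch forces a constant per-cell area where the nominal "~1 km² per
cell" convention must be mimicked exactly.

If either class is missing from a training split (a real possibility at
15 presences) the split is redrawn and counted. With presences scarcer
than 1:5 against background a note is logged: the 0.95 vote threshold is
only meaningful when the classes separate strongly.

## The physiological scenario

The measured relative WUE gain f (default 0.147) is translated into
climate space by multiplying the two precipitation-amount layers BIO12
(annual) and BIO19 (coldest quarter) by (1 − f): the inoculated tree
behaves as if the same site offered proportionally more water, or
equivalently as if it tolerated proportionally drier sites.

The scenario semantics deserve care, because three readings are possible.
The default (`scenario_mode = "reduced-presences"`) extracts presence
feature vectors from the reduced stack while background vectors and the
projection grid stay original: the learned climate envelope shifts toward
drier values and is then asked where on the *real* landscape it holds.
This is the only reading under which the scenario can expand the range
into drier terrain; rescaling the projection grid together with the
presences (`"project-on-reduced"`, provided for sensitivity analysis)
largely relabels the same cells, and rescaling the grid alone would be a
climate-change projection, not an inoculation scenario. The expansion
ratio is the modified over the baseline mean per-iteration area, with a
shared seed so that f = 0 reproduces the baseline bit for bit and returns
exactly 1.

## Survival and diversity stages

The survival stage is a from-first-principles product-limit estimator and
two-group Mantel–Haenszel log-rank test. S(t) multiplies (1 − dᵢ/nᵢ)
over death times; censored individuals leave the risk set after their
time (deaths precede censorings at ties); Greenwood's formula supplies
standard errors; the log-rank statistic sums hypergeometric
observed-minus-expected deaths with variance d(n₁/n)(n₂/n)(n−d)/(n−1) and
refers (O₁−E₁)²/ΣV to χ²₁. Median survival is the smallest death time
with S ≤ 0.5. p-values are floored at the smallest positive double rather
than reported as 0. The test suite checks both against the `survival`
package on random cohorts (S(t) to 1e−10, χ² to 1e−8); the package never
calls it in the implementation.

The diversity stage computes, per sample with relative abundances pᵢ over
nonzero taxa: Shannon H = −Σ pᵢ ln pᵢ (natural log throughout), observed
richness S, Simpson dominance D = Σ pᵢ², evenness E = e^H / S
(Buzas–Gibson), bias-corrected Chao1 = S + F₁(F₁−1)/(2(F₂+1)) (defined at
F₂ = 0), and the Chao–Lee ACE with rare-taxon cutoff 10 (ACE = S when no
taxon is rare; Chao1 when the rare-class coverage is zero). Buzas–Gibson
evenness rather than Pielou's J is a deliberate choice: for a community
with H ≈ 7.09 and S ≈ 3963, e^H/S ≈ 0.30 while J ≈ 0.86, and only the
former magnitude is consistent with the evenness values such tables
report alongside near-zero dominance; Pielou's J remains available by
computing it from the returned H and S. Bray–Curtis dissimilarity
BC = 1 − 2Σmin(aᵢ,bᵢ)/(Σa+Σb) feeds a classical PCoA (double-centering of
squared distances, symmetric eigendecomposition, coordinates scaled by
√λ on positive axes); negative eigenvalues — expected for Bray–Curtis —
are reported, never silently dropped. No rarefaction is applied by
default; `rarefy_table()` subsamples to a stated depth with a stated seed
when wanted.

Group comparisons delegate to base R's reference implementations behind a
single surface: `compare_groups()` runs one-way ANOVA + Tukey HSD
(parametric track) or Kruskal–Wallis + pairwise Mann–Whitney
(Bonferroni-adjusted by default; exact for small tie-free samples);
`bartlett_test()` wraps the variance-homogeneity check with guards;
`taxon_ttests()` runs per-taxon Welch t-tests on relative abundances with
the Bonferroni cap min(1, m·p), flagging zero-variance taxa as degenerate
with p = 1 rather than "significant". The choice between the parametric
and rank-based track is the caller's, made explicitly — mirroring the
usual manual assumption-checking workflow; normality screening itself is
out of scope.

## The synthetic-data layer: what it emulates, and what it does not

`make_virtual_landscape()` builds eight co-registered layers over a
2° × 2° lon/lat window (73–71° W, 36.5–34.5° S): each is a deterministic
latitudinal gradient plus a smoothed-white-noise random field
(moving-average kernel; a formal Gaussian-process draw would add a
dependency without changing what the validation needs — spatial
autocorrelation at a controllable scale). Temperature roles increase
northward, precipitation roles southward, as on the central-Chilean
coast. Three design features matter and are worth stating openly:

* **Dry-skewed precipitation.** Annual precipitation follows a power-law
  profile (P(BIO12 ≥ x) ∝ x⁻⁴ between 300 and 1100 mm): wet cells are
  geographically rare, dry cells abundant — the regime of a Mediterranean
  range edge, where the wet extreme is confined to a small fraction of the
  region. This is not cosmetic. A scenario that shifts the learned
  precipitation envelope toward drier values adds cells in proportion to
  how common drier climates are; on a landscape where precipitation is
  uniformly distributed over cells the added and lost margins cancel and
  no expansion signal exists to detect. The dry-skew is what gives the
  ground-truth property (lower water requirement ⇒ larger suitable area)
  room to express itself, for the real species as for the virtual one.
* **Weakly coupled ancillary layers.** BIO19 tracks BIO12 tightly
  (r ≈ 0.95); BIO18 (summer precipitation, scarce in a winter-rain
  climate) and BIO15 only loosely; the four temperature layers vary
  little across the 2° strip relative to their fine-scale (kernel 3)
  topographic noise. If every layer redundantly encoded latitude, the
  forest would memorise the wet zone's full eight-dimensional signature,
  and a scenario that shifts only BIO12/BIO19 would produce feature
  vectors matching no real cell — an artifact of collinearity, not
  biology. Real WorldClim layers over a small coastal window are closer
  to the weakly-coupled case than to perfect collinearity.
* **Background sparsity at the protocol's scale.** The protocol fixes
  100 background points; on a 2° window of 30-arc-second cells that is
  ~0.2% of cells. The validation replicates therefore run on grids of
  comparable cell counts (200–240 per side). This matters because the
  0.95 vote rule makes suitable area a near-unanimity region whose extent
  is set by the distance to the nearest background point in climate
  space; at unrealistically dense background (the same 100 points on a
  50 × 50 grid) background caps the shifted envelope everywhere and the
  expansion property is smothered. The packaged fixture keeps the
  realistic sparsity.

The virtual species are products of per-layer responses —
gaussian(optimum, width) for temperature roles, logistic(midpoint, slope)
for precipitation roles — so the true suitability surface, true suitable
area at any threshold, and the direction of any scenario are known
analytically. Two are packaged: `wet_margin_species()` (steep logistic
precipitation requirement near the regional maximum; a range-restricted
endemic used for the scenario studies) and `broad_niche_species()`
(midpoint mid-gradient; suitability varies over much of the landscape,
used for recovery studies, where rank agreement over all cells is the
score and a species that is ~0 almost everywhere would make the score
mostly noise). Presences are drawn at cell centers with probability
proportional to suitability (without replacement by default; a
bernoulli/with-replacement mode exists); background uniformly over cells
valid in all layers. Real occurrence data are census fragments, not a
probability sample — the weighted draw is a modelling choice, stated here
once.

`simulate_survival_cohort()` draws exponential (optionally Weibull) death
times per arm and records each death at the first field visit at or after
it (visit grid 15, 30, 60, 90, 180, 342, 410, 733 days; day 0 records no
events; survivors are right-censored at day 733). The default hazards,
0.009/day (control) and 0.003/day (inoculated), put 50% mortality at
~2.5 and ~8 months respectively — a 3:1 hazard ratio of the size the
field experiment detected. The downstream test treats the visit-grid
times as exact rather than interval-censored; the calibration study below
shows the type-I error survives that simplification at this schedule.

`simulate_count_table()` draws per-group taxon base abundances
log-normal(0, σ) and per-sample multinomial counts at fixed depth
(default: 3 groups × 5 samples, 200 taxa, 20,000 reads). σ directly
controls evenness (larger σ → stronger dominance); the default makes the
non-inoculated group slightly less even, the direction the ECM tables
show. Not emulated, deliberately: phylogenetic structure among taxa,
overdispersion beyond the multinomial (no Dirichlet layer),
spatially-correlated survival, within-cell occurrence jitter, and any
land/sea mask. Passing tests therefore demonstrate that the *statistical
machinery* is correct and directionally sensitive under known truth — not
that real rasters, field cohorts or amplicon tables behave this simply.

## Numerical and policy choices

Half-open cell membership ([west, west+cs) × (south, south+cs]) so every
point belongs to exactly one cell; points on nodata in any layer are
dropped and counted, never imputed. Thresholding is inclusive (≥) at
every area rule. Per-iteration seeds derive linearly from the config
seed, and per-stage seeds from the global seed by fixed offsets, so any
stage or iteration can be re-run in isolation; every derived seed stays
below 2³¹. The Kruskal–Wallis statistic carries the tie correction;
Mann–Whitney switches from exact enumeration to the corrected normal
approximation exactly where base R does. The log-rank variance term is
zero when a risk set has a single member. PCoA's eigenvalue cutoff for
"positive" is a relative 1e−12 of the leading eigenvalue.

## Problem sizes used by the validation studies

Recovery: 100 × 100 cells, 50 presences, 100 background, B = 25,
summarised as the median Spearman correlation over 5 seeded landscape
realizations (single realizations vary by ±0.1). Scenario direction: 20
replicate worlds of 240 × 240 cells (the cell count of a 2° window at 30
arc-seconds), 50 presences, 100 background, B = 8; the per-iteration
count is held below the production default because the replicate axis,
not the iteration axis, carries the uncertainty being measured. Survival
calibration: 2000 null cohorts and 1000 hazard-ratio-3 cohorts at the
50 + 50 design. Diversity: formula checks are exact; estimator
invariants run on 1000 random samples. The packaged demo
(`make_fixtures()` + `run_all()`) uses B = 10 and completes in seconds.

## Known limitations

The expansion ratio is a stochastic pipeline property: individual
replicate worlds can and do return ratios below 1 (roughly one world in
ten under the packaged conditions), typically when background points land
inside the shifted envelope while sparing the baseline's; only the
replicate ensemble is meaningful. The 0.95 vote threshold makes areas
sensitive to single background points — an inherited property of the
protocol, not a bug, and the reason both mean ± SD and ensemble-map areas
are reported. GeoTIFF I/O is not provided; the ESRI ASCII grid format
covers the pipeline end to end. The log-rank test is unstratified: the
field design planted seedlings in pairs, and a paired/stratified variant
would be the natural extension. Chao1/ACE behave as designed only on raw
(non-denoised) counts; on heavily denoised tables with no singletons they
collapse to S, the pattern heavily denoised community tables typically
show, and reproduced here.
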