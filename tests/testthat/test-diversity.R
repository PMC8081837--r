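# Alpha-diversity indexes, Bray-Curtis/PCoA and group tests; vegan and
# stats::cmdscale serve as independent oracles.

test_that("alpha indexes reproduce hand-computed toy values exactly", {
  m <- matrix(c(10, 10, 10, 10), 4, 1, dimnames = list(paste0("t", 1:4), "s1"))
  p <- alpha_profile(m)
  expect_equal(p$H, log(4))
  expect_equal(p$S, 4)
  expect_equal(p$D, 0.25)
  expect_equal(p$E, 1)
  expect_equal(p$chao1, 4)
  expect_equal(p$ace, 4 / (1 - 0))     # all rare, no singletons: S_rare/C
  # single-taxon sample
  m2 <- matrix(c(25, 0, 0), 3, 1, dimnames = list(paste0("t", 1:3), "s1"))
  p2 <- alpha_profile(m2)
  expect_equal(p2$H, 0); expect_equal(p2$S, 1)
  expect_equal(p2$D, 1); expect_equal(p2$E, 1)
  # bias-corrected Chao1 on counts (1,1,2,3,4): 5 + 2*1/(2*2) = 5.5
  m3 <- matrix(c(1, 1, 2, 3, 4), 5, 1, dimnames = list(paste0("t", 1:5), "s1"))
  expect_equal(alpha_profile(m3)$chao1, 5.5)
})

test_that("estimator invariants hold on random samples", {
  set.seed(7)
  for (i in 1:1000) {
    x <- rpois(30, exp(rnorm(30, 1.5, 1.2)))
    if (sum(x) == 0) x[1] <- 1
    m <- matrix(x, dimnames = list(sprintf("t%02d", 1:30), "s"))
    p <- alpha_profile(m)
    expect_lte(exp(p$H), p$S + 1e-9)          # hence E <= 1
    expect_gte(p$chao1, p$S)
    expect_gte(p$ace, p$S - 1e-9)
    expect_gte(p$D, 1 / p$S - 1e-12)
    expect_lte(p$D, 1)
  }
})

test_that("alpha indexes agree with vegan on random tables", {
  skip_if_not_installed("vegan")
  m <- random_counts(taxa = 40, samples = 8, seed = 3, lambda = 4)
  p <- alpha_profile(m)
  comm <- t(m)
  expect_equal(p$H, unname(vegan::diversity(comm, "shannon")), tolerance = 1e-10)
  expect_equal(p$D, unname(vegan::diversity(comm, "invsimpson"))^-1,
               tolerance = 1e-10)
  est <- vegan::estimateR(comm)
  expect_equal(p$chao1, unname(est["S.chao1", ]), tolerance = 1e-8)
  expect_equal(p$ace, unname(est["S.ACE", ]), tolerance = 1e-8)
})

test_that("dominance and Shannon move oppositely under an equalizing transfer", {
  # moving abundance from the dominant to the rarest taxon
  x <- c(60, 25, 10, 5)
  y <- c(50, 25, 10, 15)
  mx <- matrix(x, dimnames = list(paste0("t", 1:4), "s"))
  my <- matrix(y, dimnames = list(paste0("t", 1:4), "s"))
  expect_gt(alpha_profile(my)$H, alpha_profile(mx)$H)
  expect_lt(alpha_profile(my)$D, alpha_profile(mx)$D)
})

test_that("Bray-Curtis has its defining properties and matches vegan", {
  m <- random_counts(taxa = 25, samples = 6, seed = 9)
  d <- bray_curtis(m)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  # identical samples -> 0; disjoint taxa -> 1
  m2 <- cbind(a = c(5, 5, 0, 0), b = c(5, 5, 0, 0), c = c(0, 0, 3, 9))
  rownames(m2) <- paste0("t", 1:4)
  d2 <- bray_curtis(m2)
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
  skip_if_not_installed("vegan")
  ref <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  expect_equal(unname(d), unname(ref), tolerance = 1e-10)
})

test_that("PCoA reproduces classical MDS and embeds Euclidean distances", {
  set.seed(21)
  X <- matrix(rnorm(5 * 3), 5, 3)
  d <- as.matrix(dist(X))
  rownames(d) <- colnames(d) <- paste0("s", 1:5)
  ord <- pcoa(d)
  # Euclidean input: recovered coordinate distances reproduce d
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(d), tolerance = 1e-8)
  # against stats::cmdscale (sign of axes is arbitrary)
  ref <- stats::cmdscale(d, k = 3, eig = TRUE)
  expect_equal(abs(ord$coordinates), abs(ref$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ord$eigenvalues[1:3], ref$eig[1:3], tolerance = 1e-8)
  # Bray-Curtis tables: negative eigenvalues are reported, not hidden
  tab <- count_table(random_counts(taxa = 30, samples = 7, seed = 2),
                     rep(c("a", "b"), c(4, 3)))
  res <- bray_curtis_pcoa(tab)
  expect_equal(sort(res$ordination$eigenvalues, decreasing = TRUE),
               res$ordination$eigenvalues)
  expect_error(pcoa(matrix(0, 2, 2)), "at least 3")
})

test_that("Kruskal-Wallis toy grouping gives H = 7.2 and MWU enumerates", {
  gt <- compare_groups(1:9, rep(c("a", "b", "c"), each = 3), method = "kw_mwu")
  expect_equal(gt$statistic, 7.2, tolerance = 1e-10)
  expect_equal(gt$df, 2)
  expect_equal(gt$p, stats::pchisq(7.2, 2, lower.tail = FALSE))
  # exact two-sided MWU p on {1,2} vs {3,4} is 1/3
  w <- stats::wilcox.test(c(1, 2), c(3, 4))
  expect_equal(unname(w$statistic), 0)
  expect_equal(w$p.value, 1 / 3, tolerance = 1e-12)
  pw <- compare_groups(c(1, 2, 3, 4), rep(c("a", "b"), each = 2),
                       method = "kw_mwu", p_adjust = "none")$pairwise
  expect_equal(pw$p_adjusted, 1 / 3, tolerance = 1e-12)
})

test_that("Tukey HSD at two groups equals the pooled t-test", {
  set.seed(14)
  x <- c(rnorm(8, 0), rnorm(8, 1))
  g <- rep(c("a", "b"), each = 8)
  gt <- compare_groups(x, g, method = "anova_tukey")
  tt <- stats::t.test(x ~ g, var.equal = TRUE)
  expect_equal(gt$pairwise$p_adjusted, tt$p.value, tolerance = 1e-6)
  expect_equal(gt$p, tt$p.value, tolerance = 1e-10)   # F = t^2 at k = 2
  expect_error(compare_groups(rep(1, 6), rep(c("a", "b"), 3), "anova_tukey"),
               "degenerate")
})

test_that("group tests validate inputs and report adjusted >= raw", {
  set.seed(3)
  x <- rnorm(15); g <- rep(c("a", "b", "c"), each = 5)
  gt <- compare_groups(x, g, method = "kw_mwu", p_adjust = "bonferroni")
  raw <- sapply(list(c("a","b"), c("a","c"), c("b","c")), function(pr) {
    suppressWarnings(stats::wilcox.test(x[g == pr[1]], x[g == pr[2]])$p.value)
  })
  expect_true(all(gt$pairwise$p_adjusted >= raw - 1e-12))
  expect_error(compare_groups(x, rep("a", 15)), "two groups")
})

test_that("per-taxon Welch t-tests apply the Bonferroni cap", {
  set.seed(8)
  counts <- random_counts(taxa = 5, samples = 8, seed = 8)
  tab <- count_table(counts, rep(c("x", "y"), each = 4))
  res <- taxon_ttests(tab)
  expect_equal(nrow(res), 5)
  expect_equal(res$p_adjusted, pmin(1, 5 * res$p))
  # hand check one taxon against t.test on relative abundances
  rel <- sweep(counts, 2, colSums(counts), "/")
  tt <- stats::t.test(rel[2, 1:4], rel[2, 5:8])
  expect_equal(res$p[2], tt$p.value, tolerance = 1e-12)
  # zero-variance taxon in both groups: degenerate, p = 1
  counts2 <- matrix(c(10, 15, 25), 3, 8,
                    dimnames = list(paste0("t", 1:3), paste0("s", 1:8)))
  tab2 <- count_table(counts2, rep(c("x", "y"), each = 4))
  res2 <- taxon_ttests(tab2)
  expect_true(all(res2$degenerate))
  expect_true(all(res2$p == 1))
})

test_that("Bartlett test wraps the standard statistic with guards", {
  out <- bartlett_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p, 1, tolerance = 1e-12)
  # location invariance
  set.seed(5)
  x <- rnorm(18); g <- rep(c("a", "b", "c"), each = 6)
  shift <- x; shift[g == "b"] <- shift[g == "b"] + 100
  expect_equal(bartlett_test(x, g)$statistic,
               bartlett_test(shift, g)$statistic, tolerance = 1e-9)
  ref <- stats::bartlett.test(x, factor(g))
  expect_equal(bartlett_test(x, g)$statistic, unname(ref$statistic))
  expect_error(bartlett_test(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "zero within-group variance")
})

test_that("count tables validate, aggregate and round-trip as TSV", {
  counts <- random_counts(taxa = 6, samples = 4, seed = 1)
  expect_error(count_table(counts, c("a", "b")), "one group label")
  expect_error(count_table(-counts, rep("a", 4)), "nonnegative")
  tab <- count_table(counts, rep(c("a", "b"), each = 2))
  mapping <- setNames(rep(c("P1", "P2"), each = 3), rownames(counts))
  agg <- aggregate_taxa(tab, mapping)
  expect_equal(nrow(agg$counts), 2)
  expect_equal(colSums(agg$counts), colSums(counts))
  cp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, cp, mp)
  back <- read_count_table(cp, mp)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$groups, tab$groups)
})

test_that("rarefaction subsamples to depth deterministically", {
  tab <- simulate_count_table(taxa_n = 30, depth = 3000, seed = 4)
  r1 <- rarefy_table(tab, 1000, seed = 9)
  expect_true(all(colSums(r1$counts) == 1000))
  expect_identical(r1$counts, rarefy_table(tab, 1000, seed = 9)$counts)
  expect_true(all(r1$counts <= tab$counts))
})
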