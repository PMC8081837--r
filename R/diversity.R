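# Community-structure statistics on taxa x sample count tables: the six
# alpha-diversity indexes, Bray-Curtis dissimilarity with classical PCoA,
# and the group-comparison tests used on them. Index formulas, Bray-Curtis
# and the double-centering eigendecomposition are implemented directly;
# standard hypothesis tests call base R (aov/TukeyHSD, kruskal.test,
# wilcox.test, bartlett.test, t.test).

#' Construct a taxa-by-sample count table
#'
#' @param counts nonnegative integer matrix, taxa as rows, samples as
#'   columns, with unique row and column names.
#' @param groups character vector of group labels, one per sample (named by
#'   sample or in column order).
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, groups) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)) ||
      anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts must carry unique taxon (row) and sample (column) names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (any(colSums(counts) == 0)) stop("every sample total must be > 0")
  if (length(groups) != ncol(counts)) {
    stop("one group label per sample is required")
  }
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  groups <- stats::setNames(as.character(groups), colnames(counts))
  structure(list(counts = counts, groups = groups), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s (n=%d)", names(table(x$groups)),
                            as.integer(table(x$groups))), collapse = ", ")))
  invisible(x)
}

# Per-sample index computations on one count vector.
alpha_one <- function(x) {
  x <- x[x > 0]
  if (!length(x)) stop("empty sample: no positive counts")
  N <- sum(x)
  p <- x / N
  H <- -sum(p * log(p))
  S <- length(x)
  D <- sum(p^2)
  E <- exp(H) / S
  F1 <- sum(x == 1); F2 <- sum(x == 2)
  chao1 <- S + F1 * (F1 - 1) / (2 * (F2 + 1))   # bias-corrected, defined at F2 = 0
  # ACE, Chao-Lee, rare-taxon abundance cutoff 10
  rare <- x[x <= 10]
  S_rare <- length(rare); S_abund <- S - S_rare
  if (S_rare == 0) {
    ace <- S
  } else {
    N_rare <- sum(rare)
    C_ace <- 1 - F1 / N_rare
    if (C_ace <= 0) {
      ace <- chao1   # coverage-zero fallback
    } else {
      i <- seq_len(10)
      Fi <- vapply(i, function(k) sum(rare == k), numeric(1))
      g2 <- if (N_rare > 1) {
        max(S_rare / C_ace * sum(i * (i - 1) * Fi) / (N_rare * (N_rare - 1)) - 1, 0)
      } else 0
      ace <- S_abund + S_rare / C_ace + F1 / C_ace * g2
    }
  }
  c(H = H, S = S, D = D, E = E, chao1 = chao1, ace = ace)
}

#' Per-sample alpha-diversity profile
#'
#' For each sample with relative abundances p over its nonzero taxa:
#' Shannon H = -sum p log p (natural log), observed richness S, Simpson
#' dominance D = sum p^2, Buzas-Gibson evenness E = exp(H) / S, the
#' bias-corrected Chao1 estimator S + F1(F1-1)/(2(F2+1)) and the Chao-Lee
#' ACE estimator with rare-taxon cutoff 10 (ACE = S when no taxon is rare;
#' falls back to Chao1 when the rare-class sample coverage is zero).
#'
#' @param table a `count_table`, or a bare counts matrix.
#' @return `data.frame` with one row per sample: `sample`, `group` (if
#'   known), `H`, `S`, `D`, `E`, `chao1`, `ace`.
#' @export
alpha_profile <- function(table) {
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  prof <- t(apply(counts, 2, alpha_one))
  out <- data.frame(sample = colnames(counts),
                    group = if (inherits(table, "count_table"))
                      unname(table$groups) else NA_character_,
                    prof, row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(a, b) = 1 - 2 sum(min(a_i, b_i)) / (sum a + sum b), on raw counts.
#'
#' @param table a `count_table` or counts matrix (taxa x samples).
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  counts <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  n <- ncol(counts)
  tot <- colSums(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      bc <- 1 - 2 * sum(pmin(counts[, i], counts[, j])) / (tot[i] + tot[j])
      d[i, j] <- bc; d[j, i] <- bc
    }
  }
  d
}

#' Classical principal coordinates analysis of a distance matrix
#'
#' Double-centers the squared distances, G = -(1/2) J D^2 J with
#' J = I - 11'/n, and eigendecomposes G; coordinates on axes with positive
#' eigenvalues are the eigenvectors scaled by the square root of their
#' eigenvalue. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported, not dropped silently.
#'
#' @param d symmetric distance matrix.
#' @param k number of axes to keep (default all positive-eigenvalue axes).
#' @return object of class `ordination`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (descending, negatives included) and
#'   `proportion` (share of positive-eigenvalue variance per kept axis).
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("PCoA needs at least 3 samples")
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d^2) %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > max(ev) * 1e-12 & ev > 0)
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  axes <- pos[seq_len(k)]
  coords <- e$vectors[, axes, drop = FALSE] %*% diag(sqrt(ev[axes]), k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion = ev[axes] / sum(ev[ev > 0])),
            class = "ordination")
}

#' Bray-Curtis PCoA of a count table
#'
#' @param table a `count_table` with at least 3 samples.
#' @return list with `distance` (Bray-Curtis matrix) and `ordination`.
#' @export
bray_curtis_pcoa <- function(table) {
  d <- bray_curtis(table)
  list(distance = d, ordination = pcoa(d))
}

#' Compare an index across groups
#'
#' `method = "anova_tukey"` runs a one-way ANOVA followed by all-pairs
#' Tukey HSD; `method = "kw_mwu"` runs a Kruskal-Wallis test (with tie
#' correction) followed by pairwise Mann-Whitney U tests (exact for small
#' tie-free samples, normal approximation with continuity correction
#' otherwise), Bonferroni-adjusted by default. This mirrors the usual
#' two-track procedure: the parametric track where ANOVA assumptions hold,
#' the rank-based track where they do not — the choice of track is the
#' caller's, made explicitly via `method`.
#'
#' @param values numeric per-sample index values.
#' @param groups group label per value (>= 2 groups).
#' @param method `"anova_tukey"` or `"kw_mwu"`.
#' @param p_adjust adjustment for the pairwise MWU p-values
#'   (`"bonferroni"` default; ignored for Tukey, which carries its own
#'   family-wise adjustment).
#' @return object of class `group_test`: list with `method`, `statistic`,
#'   `df`, `p` and a `pairwise` data.frame (`pair`, `statistic`,
#'   `p_adjusted`, `adjustment`).
#' @export
compare_groups <- function(values, groups,
                           method = c("anova_tukey", "kw_mwu"),
                           p_adjust = "bonferroni") {
  method <- match.arg(method)
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least two groups are required")
  if (stats::var(values) == 0) stop("degenerate data: all values identical")
  if (method == "anova_tukey") {
    if (any(tapply(values, g, length) < 2)) {
      stop("anova_tukey needs >= 2 values per group")
    }
    fit <- stats::aov(values ~ g)
    at <- stats::anova(fit)
    tk <- stats::TukeyHSD(fit)$g
    pw <- data.frame(pair = rownames(tk), statistic = tk[, "diff"],
                     p_adjusted = tk[, "p adj"], adjustment = "tukey",
                     row.names = NULL, stringsAsFactors = FALSE)
    res <- list(method = "anova_tukey", statistic = at$`F value`[1],
                df = c(at$Df[1], at$Df[2]), p = at$`Pr(>F)`[1], pairwise = pw)
  } else {
    kw <- stats::kruskal.test(values, g)
    lv <- levels(g)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    raw <- vapply(pairs, function(pr) {
      w <- suppressWarnings(stats::wilcox.test(values[g == pr[1]],
                                               values[g == pr[2]]))
      c(w$statistic, w$p.value)
    }, numeric(2))
    pw <- data.frame(pair = vapply(pairs, paste, character(1), collapse = "-"),
                     statistic = raw[1, ],
                     p_adjusted = stats::p.adjust(raw[2, ], method = p_adjust),
                     adjustment = p_adjust, row.names = NULL,
                     stringsAsFactors = FALSE)
    res <- list(method = "kw_mwu", statistic = unname(kw$statistic),
                df = unname(kw$parameter), p = kw$p.value, pairwise = pw)
  }
  res$p <- max(res$p, .Machine$double.xmin)
  structure(res, class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(x$df, collapse = ","), x$p))
  print(x$pairwise)
  invisible(x)
}

#' Per-taxon Welch t-tests with Bonferroni correction
#'
#' Compares two groups' relative abundances taxon by taxon (typically on a
#' table aggregated to phylum level): Welch t statistic and p per taxon,
#' Bonferroni-adjusted as min(1, m p) over the m taxa tested. A taxon with
#' zero variance in both groups is flagged degenerate and reported with
#' p = 1.
#'
#' @param table a `count_table` whose samples belong to exactly two groups
#'   (or a two-group subset is selected via `groups`).
#' @param groups optional two group labels to compare (default: the two
#'   groups present).
#' @return `data.frame`: `taxon`, `t`, `p`, `p_adjusted`, `degenerate`.
#' @export
taxon_ttests <- function(table, groups = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (is.null(groups)) groups <- unique(unname(table$groups))
  if (length(groups) != 2) stop("exactly two groups are required")
  sel <- table$groups %in% groups
  counts <- table$counts[, sel, drop = FALSE]
  glab <- table$groups[sel]
  if (any(table(glab) < 2)) stop("need >= 2 samples per group")
  rel <- sweep(counts, 2, colSums(counts), "/")
  a <- rel[, glab == groups[1], drop = FALSE]
  b <- rel[, glab == groups[2], drop = FALSE]
  m <- nrow(rel)
  out <- lapply(seq_len(m), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      data.frame(taxon = rownames(rel)[i], t = if (mean(xa) == mean(xb)) 0 else NA,
                 p = 1, degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(xa, xb)   # Welch by default
      data.frame(taxon = rownames(rel)[i], t = unname(tt$statistic),
                 p = tt$p.value, degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- pmin(1, m * out$p)
  out[c("taxon", "t", "p", "p_adjusted", "degenerate")]
}

#' Bartlett test of homogeneity of variances
#'
#' @param values numeric vector.
#' @param groups group label per value; every group needs >= 2 values and
#'   positive variance.
#' @return list with `statistic`, `df`, `p`.
#' @export
bartlett_test <- function(values, groups) {
  g <- factor(groups)
  sizes <- tapply(values, g, length)
  if (nlevels(g) < 2 || any(sizes < 2)) {
    stop("bartlett_test needs >= 2 groups with >= 2 values each")
  }
  if (any(tapply(values, g, stats::var) == 0)) {
    stop("bartlett_test: zero within-group variance")
  }
  b <- stats::bartlett.test(values, g)
  list(statistic = unname(b$statistic), df = unname(b$parameter),
       p = b$p.value)
}

#' Aggregate a count table to a coarser taxonomic level
#'
#' @param table a `count_table`.
#' @param mapping named character vector mapping each taxon id to its
#'   higher-level name (e.g., phylum).
#' @return aggregated `count_table`.
#' @export
aggregate_taxa <- function(table, mapping) {
  stopifnot(inherits(table, "count_table"))
  if (!all(rownames(table$counts) %in% names(mapping))) {
    stop("mapping must cover every taxon in the table")
  }
  lev <- mapping[rownames(table$counts)]
  agg <- rowsum(table$counts, group = lev)
  count_table(agg, table$groups)
}

#' Read a taxa-by-sample count TSV (taxa as rows, sample ids as header)
#' plus a `sample<TAB>group` metadata TSV.
#'
#' @param counts_path counts TSV (first column = taxon id).
#' @param metadata_path metadata TSV with header `sample` and `group`.
#' @return a `count_table`.
#' @export
read_count_table <- function(counts_path, metadata_path) {
  counts <- as.matrix(utils::read.delim(counts_path, row.names = 1,
                                        check.names = FALSE))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(meta))) {
    stop("metadata TSV must have columns sample, group")
  }
  if (!all(colnames(counts) %in% meta$sample)) {
    stop("metadata is missing sample(s): ",
         paste(setdiff(colnames(counts), meta$sample), collapse = ", "))
  }
  count_table(counts, stats::setNames(meta$group, meta$sample)[colnames(counts)])
}

#' Write a count table as counts TSV + metadata TSV
#'
#' @param table a `count_table`.
#' @param counts_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_count_table <- function(table, counts_path, metadata_path) {
  df <- data.frame(taxon = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- data.frame(sample = names(table$groups), group = unname(table$groups))
  utils::write.table(meta, metadata_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(counts_path, metadata_path))
}
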