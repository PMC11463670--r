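#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration of the rank-sum distribution (ties handled by enumerating
#' group assignments over the observed, possibly tied, ranks) when
#' min(n1, n2) <= 8; otherwise the normal approximation with tie correction
#' and continuity correction. Pooled all-identical values give p = 1.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return two-sided p-value.
#' @export
wilcoxon_test <- function(x, y) {
  assert_that(length(x) > 0 && length(y) > 0, "both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  if (min(n1, n2) <= 8) {
    # exact: enumerate all C(n1+n2, n1) assignments of the observed ranks
    combs <- combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[combs], nrow = n1))
    mu <- mean(w_all)
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    return(min(1, p))
  }
  wilcoxon_normal_p(w_obs, r, n1, n2)
}

# normal approximation with tie and continuity correction on the rank-sum W
wilcoxon_normal_p <- function(w_obs, r, n1, n2) {
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(z, lower.tail = FALSE))
}

# Vectorized Wilcoxon over matrix rows: group1/group2 are column indices.
wilcoxon_rows <- function(mat, g1, g2) {
  sub <- mat[, c(g1, g2), drop = FALSE]
  n1 <- length(g1); n2 <- length(g2)
  apply(sub, 1, function(v) wilcoxon_test(v[seq_len(n1)], v[n1 + seq_len(n2)]))
}

#' Log2 fold change on de-logged normalized means
#'
#' log2((mean1 + pc) / (mean2 + pc)) where the means are taken over
#' expm1(ln-normalized values).
#'
#' @param mean1,mean2 non-negative de-logged group means.
#' @param pseudocount default 1.
#' @return log2 fold change (antisymmetric under group swap).
#' @export
log2_fold_change <- function(mean1, mean2, pseudocount = 1) {
  log2((mean1 + pseudocount) / (mean2 + pseudocount))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up: sort p ascending, q_i = min over j >= i of p_j m / j,
#' clipped at 1, returned in input order.
#'
#' @param p p-values in [0, 1].
#' @return FDR values.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(1, q)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Differential features between two cell groups
#'
#' Features are pre-filtered to max(pct1, pct2) >= min_pct and |log2fc| >=
#' logfc_threshold (pct = fraction of cells with count > 0), the Wilcoxon
#' rank-sum test is run on normalized values, and BH correction is applied
#' over the tested features only; significant = fdr < alpha.
#'
#' @param normalized features x cells normalized matrix.
#' @param cells_group1,cells_group2 disjoint, non-empty cell id vectors.
#' @param min_pct,logfc_threshold pre-filters (gene defaults 0.25/0.25; the
#'   peak defaults are 0.001/0.1).
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame feature, log2fc, pct1, pct2, p, fdr, significant,
#'   direction; empty when nothing passes the pre-filter.
#' @export
find_markers <- function(normalized, cells_group1, cells_group2,
                         min_pct = 0.25, logfc_threshold = 0.25, alpha = 0.05) {
  assert_that(length(cells_group1) > 0 && length(cells_group2) > 0,
              "both groups must be non-empty")
  assert_that(length(intersect(cells_group1, cells_group2)) == 0,
              "groups must be disjoint")
  x <- as.matrix(normalized)
  g1 <- match(cells_group1, colnames(x)); g2 <- match(cells_group2, colnames(x))
  assert_that(!anyNA(g1) && !anyNA(g2), "group cell(s) absent from the matrix")
  pct1 <- rowMeans(x[, g1, drop = FALSE] > 0)
  pct2 <- rowMeans(x[, g2, drop = FALSE] > 0)
  m1 <- rowMeans(expm1(x[, g1, drop = FALSE]))
  m2 <- rowMeans(expm1(x[, g2, drop = FALSE]))
  lfc <- log2_fold_change(m1, m2)
  keep <- pmax(pct1, pct2) >= min_pct & abs(lfc) >= logfc_threshold
  if (!any(keep)) {
    return(data.frame(feature = character(), log2fc = numeric(),
                      pct1 = numeric(), pct2 = numeric(), p = numeric(),
                      fdr = numeric(), significant = logical(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  p <- wilcoxon_rows(x[keep, , drop = FALSE], g1, g2)
  fdr <- bh_adjust(p)
  out <- data.frame(feature = rownames(x)[keep], log2fc = lfc[keep],
                    pct1 = pct1[keep], pct2 = pct2[keep], p = p, fdr = fdr,
                    significant = fdr < alpha,
                    direction = ifelse(lfc[keep] >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p, out$feature), ]
}

#' One-vs-rest markers per cluster
#'
#' @param normalized features x cells normalized matrix.
#' @param labels named per-cell cluster labels (>= 2 clusters).
#' @param ... passed to [find_markers()].
#' @return named list of per-cluster DiffResult tables (positive-direction
#'   markers flagged via `direction`); singleton clusters are skipped with a
#'   warning.
#' @export
find_all_markers <- function(normalized, labels, ...) {
  labs <- sort(unique(labels))
  assert_that(length(labs) >= 2, "need at least two clusters")
  cells <- names(labels)
  out <- list()
  for (l in labs) {
    in_l <- cells[labels == l]
    if (length(in_l) < 2) {
      warning(sprintf("cluster %s is a singleton; skipped", l))
      next
    }
    out[[as.character(l)]] <- find_markers(normalized, in_l,
                                           setdiff(cells, in_l), ...)
  }
  out
}

#' Annotate peaks by genomic feature
#'
#' Promoter if the peak overlaps [TSS + tss_region[1], TSS + tss_region[2]]
#' of any gene (strand-aware); else exon if overlapping a supplied exon
#' interval; else intron on gene-body overlap; else distal_intergenic.
#' Precedence promoter > exon > intron > distal.
#'
#' @param peaks peak data.frame.
#' @param genes gene model table (non-empty).
#' @param tss_region window around the TSS (default c(-3000, 3000)).
#' @param exons optional exon interval data.frame.
#' @return data.frame peak_id, category.
#' @export
annotate_peaks <- function(peaks, genes, tss_region = c(-3000, 3000),
                           exons = NULL) {
  assert_that(nrow(genes) > 0, "empty gene table")
  pgr <- as_granges(peaks)
  upstream <- ifelse(genes$strand == "-", -tss_region[2], tss_region[1])
  downstream <- ifelse(genes$strand == "-", -tss_region[1], tss_region[2])
  prom <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(
    start = pmax(1, genes$tss + upstream + 1), end = genes$tss + downstream + 1))
  cat <- rep("distal_intergenic", nrow(peaks))
  body_hit <- GenomicRanges::countOverlaps(pgr, as_granges(genes)) > 0
  cat[body_hit] <- "intron"
  if (!is.null(exons) && nrow(exons) > 0) {
    ex_hit <- GenomicRanges::countOverlaps(pgr, as_granges(exons)) > 0
    cat[ex_hit] <- "exon"
  }
  prom_hit <- GenomicRanges::countOverlaps(pgr, prom) > 0
  cat[prom_hit] <- "promoter"
  data.frame(peak_id = peaks$peak_id, category = cat, stringsAsFactors = FALSE)
}

#' Gene-set over-representation (hypergeometric + BH)
#'
#' p = P(X >= k) for X ~ Hypergeom(N = |universe|, K = |set cap universe|,
#' n = |hits|); BH across sets.
#'
#' @param hits hit genes (subset of universe).
#' @param universe background gene ids (non-empty).
#' @param gene_sets named list of gene-id vectors.
#' @return data.frame set, overlap, size, p, fdr.
#' @export
geneset_ora <- function(hits, universe, gene_sets) {
  assert_that(length(universe) > 0, "empty universe")
  assert_that(all(hits %in% universe), "hits must be a subset of the universe")
  N <- length(universe); n <- length(hits)
  res <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], universe)
    k <- length(intersect(hits, set)); K <- length(set)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, overlap = k, size = K, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out
}
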