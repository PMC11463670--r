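#' Gated cluster mean for a (possibly heteromeric) complex
#'
#' The per-subunit cluster mean is computed on normalized expression; the
#' complex mean is the minimum over subunits (least-expressed-subunit rule);
#' the result is gated to 0 when any subunit is expressed (count > 0) in
#' fewer than `min_frac` of the cluster's cells.
#'
#' @param normalized genes x cells normalized matrix.
#' @param cluster_cells cell ids of the cluster.
#' @param subunits gene ids of the complex (all must be present).
#' @param min_frac expression-fraction gate (default 0.1).
#' @return list(mean, gated, pct per subunit).
#' @export
cluster_complex_mean <- function(normalized, cluster_cells, subunits,
                                 min_frac = 0.1) {
  missing <- setdiff(subunits, rownames(normalized))
  assert_that(length(missing) == 0, "missing gene(s): %s",
              paste(missing, collapse = ", "))
  x <- as.matrix(normalized[subunits, cluster_cells, drop = FALSE])
  means <- rowMeans(x)
  pct <- rowMeans(x > 0)
  gated <- any(pct < min_frac)
  list(mean = if (gated) 0 else min(means), gated = gated,
       pct = pct, subunit_means = means)
}

#' Permutation test for a ligand-receptor interaction
#'
#' statistic = (ligand complex mean in the sender cluster + receptor complex
#' mean in the receiver cluster) / 2; the null permutes the cluster labels
#' over the union's cells `n_perm` times; p = (1 + #{null >= observed}) /
#' (1 + n_perm). Pairs gated on either side get p = 1.
#'
#' @param normalized genes x cells normalized matrix.
#' @param sender_cells,receiver_cells disjoint clusters of >= 10 cells each.
#' @param ligand_subunits,receptor_subunits gene-id vectors.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param min_frac expression-fraction gate (default 0.1).
#' @param alpha significance level (default 0.05).
#' @return InteractionResult data.frame row.
#' @export
interaction_test <- function(normalized, sender_cells, receiver_cells,
                             ligand_subunits, receptor_subunits,
                             n_perm = 1000, seed = 1L, min_frac = 0.1,
                             alpha = 0.05) {
  assert_that(length(intersect(sender_cells, receiver_cells)) == 0,
              "sender and receiver must be disjoint")
  assert_that(length(sender_cells) >= 10 && length(receiver_cells) >= 10,
              "each cluster needs >= 10 cells")
  lig <- cluster_complex_mean(normalized, sender_cells, ligand_subunits, min_frac)
  rec <- cluster_complex_mean(normalized, receiver_cells, receptor_subunits, min_frac)
  observed <- (lig$mean + rec$mean) / 2
  gated <- lig$gated || rec$gated
  if (gated || n_perm == 0) {
    p <- 1
  } else {
    set.seed(as.integer(seed))
    cells <- c(sender_cells, receiver_cells)
    ns <- length(sender_cells)
    L <- as.matrix(normalized[ligand_subunits, cells, drop = FALSE])
    R <- as.matrix(normalized[receptor_subunits, cells, drop = FALSE])
    null_stat <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(cells))
      s_idx <- idx[seq_len(ns)]; r_idx <- idx[-seq_len(ns)]
      lm <- min(rowMeans(L[, s_idx, drop = FALSE]))
      rm_ <- min(rowMeans(R[, r_idx, drop = FALSE]))
      (lm + rm_) / 2
    }, 0)
    p <- (1 + sum(null_stat >= observed)) / (1 + n_perm)
  }
  data.frame(interaction_mean = observed, p_value = p,
             significant = !gated & p < alpha,
             ligand_mean = lig$mean, receptor_mean = rec$mean,
             ligand_min_pct = min(lig$pct), receptor_min_pct = min(rec$pct),
             gated = gated, stringsAsFactors = FALSE)
}

#' Run the interaction test over a ligand-receptor table
#'
#' @param normalized genes x cells normalized matrix.
#' @param sender_cells,receiver_cells cluster cell ids.
#' @param lr_table data.frame pair_id, ligand, receptor (comma-separated
#'   subunits), pathway.
#' @param n_perm,seed,min_frac,alpha passed to [interaction_test()].
#' @return data.frame with one row per pair (missing genes skipped with a
#'   reason).
#' @export
test_lr_table <- function(normalized, sender_cells, receiver_cells, lr_table,
                          n_perm = 1000, seed = 1L, min_frac = 0.1,
                          alpha = 0.05) {
  rows <- list()
  for (i in seq_len(nrow(lr_table))) {
    lig <- strsplit(lr_table$ligand[i], ",")[[1]]
    rec <- strsplit(lr_table$receptor[i], ",")[[1]]
    if (!all(c(lig, rec) %in% rownames(normalized))) {
      rows[[i]] <- data.frame(pair_id = lr_table$pair_id[i],
                              pathway = lr_table$pathway[i],
                              interaction_mean = NA_real_, p_value = NA_real_,
                              significant = FALSE, skipped = "gene missing",
                              stringsAsFactors = FALSE)
      next
    }
    r <- interaction_test(normalized, sender_cells, receiver_cells, lig, rec,
                          n_perm = n_perm, seed = derive_seed(seed, lr_table$pair_id[i]),
                          min_frac = min_frac, alpha = alpha)
    rows[[i]] <- cbind(data.frame(pair_id = lr_table$pair_id[i],
                                  pathway = lr_table$pathway[i],
                                  stringsAsFactors = FALSE),
                       r[, c("interaction_mean", "p_value", "significant")],
                       skipped = "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count significant interactions per condition
#'
#' @param results named list of [test_lr_table()] outputs, one per condition
#'   (names like "XX.E11.5"); conditions pair XX/XY per stage for the Venn
#'   partition.
#' @param alpha significance level (default 0.05).
#' @return list(counts per condition, pathway_counts, venn per stage with
#'   XX_only / XY_only / shared).
#' @export
count_interactions <- function(results, alpha = 0.05) {
  sig_sets <- lapply(results, function(r)
    r$pair_id[!is.na(r$p_value) & r$p_value < alpha & r$significant])
  counts <- data.frame(condition = names(results),
                       n_significant = lengths(sig_sets),
                       stringsAsFactors = FALSE)
  pw <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    sig <- r[r$pair_id %in% sig_sets[[nm]], , drop = FALSE]
    if (nrow(sig) == 0) return(NULL)
    agg <- as.data.frame(table(sig$pathway), stringsAsFactors = FALSE)
    names(agg) <- c("pathway", "n")
    agg$condition <- nm
    agg
  })
  pathway_counts <- do.call(rbind, pw)
  stages <- unique(sub("^(XX|XY)\\.", "", names(results)))
  venn <- lapply(stages, function(st) {
    xx <- sig_sets[[paste0("XX.", st)]]; xy <- sig_sets[[paste0("XY.", st)]]
    if (is.null(xx)) xx <- character(); if (is.null(xy)) xy <- character()
    c(XX_only = length(setdiff(xx, xy)), XY_only = length(setdiff(xy, xx)),
      shared = length(intersect(xx, xy)))
  })
  names(venn) <- stages
  list(counts = counts, pathway_counts = pathway_counts, venn = venn)
}
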