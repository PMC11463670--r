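#' Triage candidate transcription factors
#'
#' A TF is a candidate iff (a) it is differentially expressed between sexes
#' (fdr < alpha, |log2fc| >= de_logfc); (b) it is germline-enriched (DE in
#' PGCs vs somatic cells, positive direction, fdr < alpha); (c) its motif is
#' enriched in the DA-peaks-linked-to-DEGs set (p < alpha); and (d) its mean
#' motif-activity z is positive in the focal population. TFs without a motif
#' mapping are skipped with a warning. Ordered by enrichment p.
#'
#' @param sex_de DiffResult table for the between-sex contrast.
#' @param germ_de DiffResult table for PGC vs somatic (positive = PGC-high).
#' @param enrichment [motif_enrichment()] table.
#' @param deviations [chromvar_deviations()] result.
#' @param tf2motif named map TF gene -> motif id.
#' @param focal_cells cell ids of the focal population (for criterion d).
#' @param alpha significance level (default 0.05).
#' @param de_logfc sex-DE fold threshold (default 0.25).
#' @return TFCandidate data.frame with per-criterion flags and `passes_all`.
#' @export
triage_tfs <- function(sex_de, germ_de, enrichment, deviations, tf2motif,
                       focal_cells, alpha = 0.05, de_logfc = 0.25) {
  tfs <- names(tf2motif)
  rows <- list()
  for (tf in tfs) {
    motif <- tf2motif[[tf]]
    if (!motif %in% enrichment$motif_id) {
      warning(sprintf("TF %s has no motif enrichment entry; skipped", tf))
      next
    }
    sd_row <- sex_de[sex_de$feature == tf, ]
    gd_row <- germ_de[germ_de$feature == tf, ]
    en_row <- enrichment[enrichment$motif_id == motif, ]
    is_de <- nrow(sd_row) > 0 && sd_row$fdr[1] < alpha &&
      abs(sd_row$log2fc[1]) >= de_logfc
    is_germ <- nrow(gd_row) > 0 && gd_row$fdr[1] < alpha && gd_row$log2fc[1] > 0
    is_enr <- en_row$p[1] < alpha
    zrow <- deviations$z[motif, intersect(focal_cells, colnames(deviations$z))]
    mean_z <- mean(zrow, na.rm = TRUE)
    pass <- is_de && is_germ && is_enr && isTRUE(mean_z > 0)
    reason <- c(if (!is_de) "not sex-DE", if (!is_germ) "not germline-enriched",
                if (!is_enr) "motif not enriched",
                if (!isTRUE(mean_z > 0)) "non-positive motif activity")
    rows[[tf]] <- data.frame(
      tf = tf, motif_id = motif,
      is_de_between_sexes = is_de,
      sex_log2fc = if (nrow(sd_row)) sd_row$log2fc[1] else NA_real_,
      sex_fdr = if (nrow(sd_row)) sd_row$fdr[1] else NA_real_,
      is_germline_enriched = is_germ,
      germ_fdr = if (nrow(gd_row)) gd_row$fdr[1] else NA_real_,
      motif_enriched = is_enr, enrichment_p = en_row$p[1],
      enrichment_fdr = en_row$fdr[1],
      mean_motif_activity_z = mean_z,
      passes_all = pass,
      reason = if (pass) "" else paste(reason, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$enrichment_p, out$tf), ]
}

#' Assign target genes to candidate TFs
#'
#' An edge TF -> gene is created when a retained peak-gene link to a DE gene
#' has the TF's motif hit inside the linked peak; duplicate (tf, gene) edges
#' collapse to the best-p peak. Per-TF target coverage = |targets| / |DEGs
#' with >= 1 retained link|.
#'
#' @param candidates [triage_tfs()] table (rows with `passes_all` are used).
#' @param links LinkResult table filtered/filterable to DE genes.
#' @param hits motif hit data.frame (peak_id, motif_id, offset, strand).
#' @param degs DE gene ids.
#' @return list(edges data.frame, coverage data.frame).
#' @export
assign_targets <- function(candidates, links, hits, degs) {
  cand <- candidates[candidates$passes_all, , drop = FALSE]
  lk <- links[links$retained & links$gene_id %in% degs, , drop = FALSE]
  denom <- length(unique(lk$gene_id))
  edge_rows <- list()
  for (i in seq_len(nrow(cand))) {
    h <- hits[hits$motif_id == cand$motif_id[i], , drop = FALSE]
    sub <- lk[lk$peak_id %in% h$peak_id, , drop = FALSE]
    if (nrow(sub) == 0) next
    sub <- sub[order(sub$p_value), ]
    sub <- sub[!duplicated(sub$gene_id), ]
    off <- h$offset[match(sub$peak_id, h$peak_id)]
    edge_rows[[i]] <- data.frame(
      tf = cand$tf[i], target = sub$gene_id, peak_id = sub$peak_id,
      motif_offset = off, link_z = sub$z_score, link_p = sub$p_value,
      stringsAsFactors = FALSE)
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(tf = character(), target = character(), peak_id = character(),
               motif_offset = integer(), link_z = numeric(), link_p = numeric())
  rownames(edges) <- NULL
  coverage <- data.frame(
    tf = cand$tf,
    n_targets = vapply(cand$tf, function(t) sum(edges$tf == t), 0L),
    denominator = rep(denom, nrow(cand)), stringsAsFactors = FALSE)
  coverage$coverage <- ifelse(coverage$denominator > 0,
                              coverage$n_targets / coverage$denominator, NA_real_)
  list(edges = edges, coverage = coverage)
}

#' TF x TF cross-regulation incidence
#'
#' Entry (A, B) = 1 iff A's motif occurs in a retained linked peak of gene B
#' or in B's promoter (TSS +/- tss_region); the diagonal is reported
#' (self-regulation allowed).
#'
#' @param candidates [triage_tfs()] table (all rows used).
#' @param links LinkResult table.
#' @param hits motif hit data.frame.
#' @param genes gene model table (must contain the TF genes).
#' @param peaks peak data.frame (for promoter overlap).
#' @param tss_region promoter window (default c(-3000, 3000)).
#' @return binary TF x TF matrix.
#' @export
cross_regulation <- function(candidates, links, hits, genes, peaks,
                             tss_region = c(-3000, 3000)) {
  tfs <- candidates$tf
  assert_that(all(tfs %in% genes$gene_id),
              "candidate TF gene(s) absent from the gene model")
  inc <- matrix(0L, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  lk <- links[links$retained, , drop = FALSE]
  gsub <- genes[match(tfs, genes$gene_id), ]
  prom <- GenomicRanges::GRanges(gsub$chrom, IRanges::IRanges(
    start = pmax(1, gsub$tss + tss_region[1] + 1),
    end = gsub$tss + tss_region[2] + 1))
  pgr <- as_granges(peaks)
  prom_hits <- GenomicRanges::findOverlaps(pgr, prom)
  prom_peaks <- split(peaks$peak_id[S4Vectors::queryHits(prom_hits)],
                      tfs[S4Vectors::subjectHits(prom_hits)])
  for (a in tfs) {
    ha <- hits$peak_id[hits$motif_id == candidates$motif_id[match(a, tfs)]]
    for (b in tfs) {
      in_link <- any(lk$peak_id[lk$gene_id == b] %in% ha)
      in_prom <- any(prom_peaks[[b]] %in% ha)
      inc[a, b] <- as.integer(in_link || isTRUE(in_prom))
    }
  }
  inc
}

#' Network summary statistics
#'
#' Per TF: number of targets, the denominator (DEGs with >= 1 retained link)
#' and the percentage; plus pairwise TF target-set overlaps.
#'
#' @param network [assign_targets()] result.
#' @param degs DE gene ids.
#' @param links LinkResult table.
#' @return list(per_tf data.frame, overlaps matrix).
#' @export
network_summary <- function(network, degs, links) {
  lk <- links[links$retained & links$gene_id %in% degs, , drop = FALSE]
  denom <- length(unique(lk$gene_id))
  tfs <- unique(network$edges$tf)
  per_tf <- data.frame(
    tf = tfs,
    n_targets = vapply(tfs, function(t) sum(network$edges$tf == t), 0L),
    denominator = rep(denom, length(tfs)), stringsAsFactors = FALSE)
  per_tf$percent <- ifelse(per_tf$denominator > 0,
                           100 * per_tf$n_targets / per_tf$denominator, NA_real_)
  ov <- matrix(0L, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  for (a in tfs) for (b in tfs)
    ov[a, b] <- length(intersect(network$edges$target[network$edges$tf == a],
                                 network$edges$target[network$edges$tf == b]))
  list(per_tf = per_tf, overlaps = ov)
}
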