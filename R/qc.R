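#' Per-cell RNA QC metrics
#'
#' @param rna CountMatrix (genes x cells).
#' @param genes gene model table covering every feature (needs
#'   `is_mitochondrial`).
#' @return data.frame with `cell_id`, `n_count_rna`, `pct_mito` (percent;
#'   0 for all-zero cells).
#' @export
compute_rna_qc <- function(rna, genes) {
  missing <- setdiff(rownames(rna), genes$gene_id)
  assert_that(length(missing) == 0, "feature(s) absent from gene table: %s",
              paste(head(missing, 3), collapse = ", "))
  mito <- genes$gene_id[genes$is_mitochondrial]
  total <- Matrix::colSums(rna)
  mt <- Matrix::colSums(rna[rownames(rna) %in% mito, , drop = FALSE])
  data.frame(cell_id = colnames(rna),
             n_count_rna = as.numeric(total),
             pct_mito = ifelse(total == 0, 0, 100 * mt / total),
             stringsAsFactors = FALSE)
}

#' Per-cell nucleosome signal
#'
#' Ratio of mono-nucleosomal (length 147-294 bp) to sub-nucleosomal
#' (< 147 bp) fragment counts; 0 for cells without fragments.
#'
#' @param fragments fragments data.frame.
#' @param cell_ids cells to report (cells absent from the file get 0).
#' @return named numeric vector over `cell_ids`.
#' @export
compute_nucleosome_signal <- function(fragments, cell_ids) {
  out <- setNames(numeric(length(cell_ids)), cell_ids)
  if (nrow(fragments) == 0) return(out)
  len <- fragments$end - fragments$start
  keep <- fragments$barcode %in% cell_ids
  mono <- tapply(as.numeric(len >= 147 & len <= 294)[keep],
                 fragments$barcode[keep], sum)
  sub <- tapply(as.numeric(len < 147)[keep], fragments$barcode[keep], sum)
  cells <- names(mono)
  out[cells] <- mono / pmax(1, sub)
  out
}

#' Per-cell TSS enrichment
#'
#' Mean per-bp fragment coverage in TSS +/- 250 bp over the mean per-bp
#' coverage in the two flank windows [TSS-2000, TSS-1900) and
#' (TSS+1900, TSS+2000], aggregated over all TSS. Zero flank coverage with a
#' nonzero center reports the sentinel 1e6; 0/0 reports 0.
#'
#' @param fragments fragments data.frame.
#' @param genes gene model table (non-empty, with `tss`).
#' @param cell_ids cells to report.
#' @return named numeric vector over `cell_ids`.
#' @export
compute_tss_enrichment <- function(fragments, genes, cell_ids) {
  assert_that(nrow(genes) > 0, "empty gene table")
  out <- setNames(numeric(length(cell_ids)), cell_ids)
  if (nrow(fragments) == 0) return(out)
  frag <- fragments[fragments$barcode %in% cell_ids, , drop = FALSE]
  if (nrow(frag) == 0) return(out)
  fgr <- as_granges(frag)
  win <- function(lo, hi) GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$tss + lo + 1, end = genes$tss + hi))
  center <- win(-250, 250)
  flank <- c(win(-2000, -1900), win(1901, 2001))
  cov_bp <- function(windows) {
    hits <- GenomicRanges::findOverlaps(fgr, windows)
    if (length(hits) == 0) return(NULL)
    ov <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(fgr)[S4Vectors::queryHits(hits)],
      GenomicRanges::ranges(windows)[S4Vectors::subjectHits(hits)]))
    tapply(ov, frag$barcode[S4Vectors::queryHits(hits)], sum)
  }
  cbp <- cov_bp(center); fbp <- cov_bp(flank)
  c_w <- sum(IRanges::width(center)); f_w <- sum(IRanges::width(flank))
  cvec <- setNames(numeric(length(cell_ids)), cell_ids)
  fvec <- cvec
  if (!is.null(cbp)) cvec[names(cbp)] <- cbp / c_w
  if (!is.null(fbp)) fvec[names(fbp)] <- fbp / f_w
  out <- ifelse(fvec > 0, cvec / fvec, ifelse(cvec > 0, 1e6, 0))
  setNames(out, cell_ids)
}

#' Filter cells on QC metrics
#'
#' A cell is retained iff all strict inequalities hold: rna_count_min <
#' n_count_rna < rna_count_max, pct_mito < pct_mito_max, atac_count_min <
#' n_count_atac < atac_count_max, nucleosome_signal < nucleosome_signal_max,
#' tss_enrichment > tss_enrichment_min. Boundary values are excluded,
#' matching the printed operators.
#'
#' @param metrics data.frame with the five metric columns plus `cell_id`.
#' @param config a [pipeline_config()].
#' @return list(retained = cell ids, exclusions = per-rule counts).
#' @export
filter_cells <- function(metrics, config = pipeline_config()) {
  rules <- list(
    rna_low = metrics$n_count_rna > config$rna_count_min,
    rna_high = metrics$n_count_rna < config$rna_count_max,
    mito = metrics$pct_mito < config$pct_mito_max,
    atac_low = metrics$n_count_atac > config$atac_count_min,
    atac_high = metrics$n_count_atac < config$atac_count_max,
    nucleosome = metrics$nucleosome_signal < config$nucleosome_signal_max,
    tss = metrics$tss_enrichment > config$tss_enrichment_min)
  keep <- Reduce("&", rules)
  exclusions <- vapply(rules, function(r) sum(!r), 0L)
  log_stage("qc", "cells in: %d, retained: %d (%s)",
            nrow(metrics), sum(keep),
            paste(names(exclusions), exclusions, sep = "=", collapse = ", "))
  list(retained = metrics$cell_id[keep], exclusions = exclusions)
}

#' Filter peaks on width, chromosome and blacklist
#'
#' Retains peaks with width strictly between `peak_width_min` and
#' `peak_width_max`, chromosome in `standard_chroms`, and zero overlap with
#' any blacklist interval.
#'
#' @param peaks peak data.frame.
#' @param standard_chroms allowed chromosome names.
#' @param blacklist optional data.frame of excluded intervals.
#' @param config a [pipeline_config()].
#' @return the retained subset of `peaks`.
#' @export
filter_peaks <- function(peaks, standard_chroms, blacklist = NULL,
                         config = pipeline_config()) {
  width <- peaks$end - peaks$start
  keep <- width > config$peak_width_min & width < config$peak_width_max &
    peaks$chrom %in% standard_chroms
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    hits <- GenomicRanges::countOverlaps(as_granges(peaks), as_granges(blacklist))
    keep <- keep & hits == 0
  }
  log_stage("qc", "peaks in: %d, retained: %d", nrow(peaks), sum(keep))
  peaks[keep, , drop = FALSE]
}

#' Default marker configuration for the cell-type triage
#' @return list of marker-id vectors.
#' @export
default_markers <- function() {
  list(
    germ_positive = c("Ddx4", "Pou5f1"),
    soma_exclusion = c("Foxl2", "Runx1", "Sox9", "Insl3", "Wt1", "Plvap",
                       "Mafb", "Pdgfra", "Nr2f2", "Tspan8", "Krt19"),
    supporting_positive = "Wt1",
    supporting_exclusion = c("Ddx4", "Pou5f1", "Plvap", "Pecam1", "Pdgfra", "Nr2f2"))
}

#' Marker-count cell-type triage
#'
#' Raw-count rules: PGC iff any germ-positive marker has count >= 1 AND every
#' soma-exclusion marker has count 0 ("RNA count < 1"); supporting iff the
#' supporting-positive marker (Wt1) has count > 1 (i.e. >= 2) AND every
#' supporting-exclusion marker has count 0. Cells matching both rules are
#' excluded as ambiguous; everything else is "other". The germ-positive
#' requirement is an OR over the germ markers (configurable via
#' `germ_rule = "all"`).
#'
#' @param rna CountMatrix of raw counts.
#' @param markers list as in [default_markers()].
#' @param germ_rule `"any"` (default) or `"all"`.
#' @return data.frame `cell_id`, `label` in {PGC, supporting, other,
#'   excluded}, `reason`.
#' @export
call_cell_types <- function(rna, markers = default_markers(), germ_rule = c("any", "all")) {
  germ_rule <- match.arg(germ_rule)
  all_markers <- unique(unlist(markers))
  missing <- setdiff(all_markers, rownames(rna))
  assert_that(length(missing) == 0, "marker gene(s) absent from matrix: %s",
              paste(missing, collapse = ", "))
  get <- function(g) as.matrix(rna[g, , drop = FALSE])
  germ <- get(markers$germ_positive)
  germ_pos <- if (germ_rule == "any") Matrix::colSums(germ >= 1) > 0
              else Matrix::colSums(germ >= 1) == nrow(germ)
  soma_clean <- Matrix::colSums(get(markers$soma_exclusion) >= 1) == 0
  supp_pos <- Matrix::colSums(get(markers$supporting_positive) > 1) > 0
  supp_clean <- Matrix::colSums(get(markers$supporting_exclusion) >= 1) == 0
  is_pgc <- germ_pos & soma_clean
  is_supp <- supp_pos & supp_clean
  label <- rep("other", ncol(rna))
  reason <- rep("no rule matched", ncol(rna))
  label[is_pgc] <- "PGC"; reason[is_pgc] <- "germ markers present, soma markers absent"
  label[is_supp] <- "supporting"; reason[is_supp] <- "Wt1 > 1, exclusion markers absent"
  # positive marker together with its exclusion markers: putative doublet
  germ_dbl <- germ_pos & !soma_clean & !is_supp
  supp_dbl <- supp_pos & !supp_clean & !is_pgc
  label[germ_dbl] <- "excluded"; reason[germ_dbl] <- "germ and somatic markers (doublet rule)"
  label[supp_dbl] <- "excluded"; reason[supp_dbl] <- "Wt1 with exclusion markers (doublet rule)"
  both <- is_pgc & is_supp
  label[both] <- "excluded"; reason[both] <- "ambiguous"
  log_stage("triage", "cells: %d, PGC: %d, supporting: %d, other: %d, excluded: %d",
            ncol(rna), sum(label == "PGC"), sum(label == "supporting"),
            sum(label == "other"), sum(label == "excluded"))
  data.frame(cell_id = colnames(rna), label = label, reason = reason,
             stringsAsFactors = FALSE)
}

#' Drop mitochondrial features
#'
#' @param rna CountMatrix.
#' @param genes gene model with `is_mitochondrial`.
#' @return the matrix without mito-flagged rows; columns untouched.
#' @export
drop_mito_features <- function(rna, genes) {
  mito <- genes$gene_id[genes$is_mitochondrial]
  out <- rna[!rownames(rna) %in% mito, , drop = FALSE]
  log_stage("qc", "features in: %d, after mito removal: %d", nrow(rna), nrow(out))
  out
}
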