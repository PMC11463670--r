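#' Rank-based module score
#'
#' Mann-Whitney-style relative-rank score of a gene signature per cell: genes
#' are ranked by descending expression (average ranks for ties), ranks above
#' `rank_ceiling` are clipped to `rank_ceiling + 1`, U = sum(signature ranks)
#' - n(n+1)/2, and score = 1 - U / (n * (ceiling - n)), clipped to [0, 1].
#' Deterministic; no sampling.
#'
#' @param normalized genes x cells normalized expression matrix.
#' @param signature gene ids (at least one present).
#' @param rank_ceiling rank clip (default 1500).
#' @return named numeric vector of per-cell scores in [0, 1].
#' @export
rank_module_score <- function(normalized, signature, rank_ceiling = 1500) {
  sig <- intersect(signature, rownames(normalized))
  assert_that(length(signature) > 0, "empty signature")
  assert_that(length(sig) > 0, "no signature gene present in the matrix")
  x <- as.matrix(normalized)
  n <- length(sig)
  scores <- apply(x, 2, function(v) {
    r <- rank(-v, ties.method = "average")
    r[r > rank_ceiling] <- rank_ceiling + 1
    u <- sum(r[sig]) - n * (n + 1) / 2
    1 - u / (n * (rank_ceiling - n))
  })
  setNames(pmin(1, pmax(0, scores)), colnames(x))
}

#' Binned-control module score
#'
#' Genes are binned into `n_bins` by average expression; for each signature
#' gene, `n_ctrl` control genes are sampled (with replacement) from its bin;
#' score = mean(signature expression) - mean(control expression) per cell.
#'
#' @param normalized genes x cells normalized expression matrix.
#' @param signature gene ids.
#' @param n_bins,n_ctrl binning and control-pool parameters.
#' @param seed integer seed for the control draw.
#' @return named numeric vector of per-cell scores.
#' @export
control_module_score <- function(normalized, signature, n_bins = 24,
                                 n_ctrl = 100, seed = 1L) {
  sig <- intersect(signature, rownames(normalized))
  assert_that(length(signature) > 0, "empty signature")
  assert_that(length(sig) > 0, "no signature gene present in the matrix")
  x <- as.matrix(normalized)
  set.seed(as.integer(seed))
  avg <- rowMeans(x)
  bin <- decile_bin(avg, n_bins)
  ctrl <- unlist(lapply(sig, function(g) {
    pool <- rownames(x)[bin == bin[match(g, rownames(x))]]
    sample(pool, n_ctrl, replace = TRUE)
  }))
  colMeans(x[sig, , drop = FALSE]) - colMeans(x[ctrl, , drop = FALSE])
}

#' Per-cell chrY fragment counts within retained chrY peaks
#'
#' Counts fragments (weighted by duplicate count) overlapping any chrY peak
#' inside the configured region (default 1-90,000,000 bp, excluding the
#' pseudoautosomal region by construction). Overlap uses the 0-based
#' half-open convention: a fragment abutting a peak end does not count.
#'
#' @param fragments fragments data.frame.
#' @param chrY_peaks peak data.frame restricted to chrY.
#' @param chrY_region length-2 numeric region bounds.
#' @param cell_ids cells to report.
#' @param chrY_name chromosome name (default "chrY").
#' @return named integer vector over `cell_ids`.
#' @export
chrY_fragment_counts <- function(fragments, chrY_peaks,
                                 chrY_region = c(1, 9e7), cell_ids,
                                 chrY_name = "chrY") {
  out <- setNames(integer(length(cell_ids)), cell_ids)
  pk <- chrY_peaks[chrY_peaks$chrom == chrY_name &
                   chrY_peaks$start >= chrY_region[1] &
                   chrY_peaks$end <= chrY_region[2], , drop = FALSE]
  fr <- fragments[fragments$chrom == chrY_name &
                  fragments$barcode %in% cell_ids, , drop = FALSE]
  if (nrow(pk) == 0 || nrow(fr) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(as_granges(fr), as_granges(pk))
  if (length(hits) == 0) return(out)
  agg <- tapply(fr$count[S4Vectors::queryHits(hits)],
                fr$barcode[S4Vectors::queryHits(hits)], sum)
  out[names(agg)] <- as.integer(agg)
  out
}

#' Assign chromosomal sex from module scores and chrY fragment counts
#'
#' Thresholds are set from labeled reference cells (in the gonad data, the
#' E13.5 libraries; in the synthetic setting, the generator's E13.5
#' analogues). With the default tolerant band, male_cut = mean(score | XY
#' reference) - 1 sd and female_cut = mean(score | XX reference) + 1 sd; a
#' cell is claimed male when its score is at or above male_cut, female when
#' at or below female_cut (nearest reference mean when the bands overlap). A
#' male claim is demoted to ambiguous when chrY_count = 0 or score <
#' male_cut; a female claim when chrY_count > 1 or score > female_cut.
#' `cut_direction = "strict"` instead places male_cut at mean + 1 sd and
#' female_cut at mean - 1 sd.
#'
#' @param scores named per-cell module scores.
#' @param chrY_counts named per-cell chrY fragment counts (same cells).
#' @param reference list with `XY` and `XX` character vectors of reference
#'   cell ids (each of size >= 2).
#' @param cut_direction `"tolerant"` (default) or `"strict"`.
#' @return data.frame `cell_id`, `call` in {XX, XY, ambiguous},
#'   `module_score`, `chrY_count`, `male_cut`, `female_cut`.
#' @export
assign_sex <- function(scores, chrY_counts, reference,
                       cut_direction = c("tolerant", "strict")) {
  cut_direction <- match.arg(cut_direction)
  assert_that(length(reference$XY) >= 2 && length(reference$XX) >= 2,
              "each reference set needs >= 2 cells (sd undefined otherwise)")
  cells <- names(scores)
  assert_that(all(cells == names(chrY_counts)), "score/count cell sets differ")
  m_xy <- mean(scores[reference$XY]); s_xy <- sd(scores[reference$XY])
  m_xx <- mean(scores[reference$XX]); s_xx <- sd(scores[reference$XX])
  if (cut_direction == "tolerant") {
    male_cut <- m_xy - s_xy; female_cut <- m_xx + s_xx
  } else {
    male_cut <- m_xy + s_xy; female_cut <- m_xx - s_xx
  }
  claim <- ifelse(scores >= male_cut & scores > female_cut, "XY",
           ifelse(scores <= female_cut & scores < male_cut, "XX",
           ifelse(abs(scores - m_xy) < abs(scores - m_xx), "XY", "XX")))
  call <- claim
  call[claim == "XY" & (chrY_counts == 0 | scores < male_cut)] <- "ambiguous"
  call[claim == "XX" & (chrY_counts > 1 | scores > female_cut)] <- "ambiguous"
  log_stage("sex", "cells: %d, XY: %d, XX: %d, ambiguous: %d (male_cut=%.4f, female_cut=%.4f)",
            length(cells), sum(call == "XY"), sum(call == "XX"),
            sum(call == "ambiguous"), male_cut, female_cut)
  data.frame(cell_id = cells, call = call,
             module_score = unname(scores), chrY_count = unname(chrY_counts),
             male_cut = male_cut, female_cut = female_cut,
             stringsAsFactors = FALSE)
}
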