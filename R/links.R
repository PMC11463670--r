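#' Candidate peak-gene pairs within a distance
#'
#' Pairs whose peak midpoint lies within `max_distance` of the gene TSS on
#' the same chromosome.
#'
#' @param peaks peak data.frame.
#' @param genes gene model table.
#' @param max_distance default 500 kb.
#' @return data.frame peak_id, gene_id, distance.
#' @export
candidate_pairs <- function(peaks, genes, max_distance = 5e5) {
  out <- list()
  mid <- (peaks$start + peaks$end) / 2
  for (ch in intersect(unique(peaks$chrom), unique(genes$chrom))) {
    pi <- which(peaks$chrom == ch); gi <- which(genes$chrom == ch)
    d <- abs(outer(mid[pi], genes$tss[gi], "-"))
    hit <- which(d <= max_distance, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out[[ch]] <- data.frame(peak_id = peaks$peak_id[pi[hit[, 1]]],
                            gene_id = genes$gene_id[gi[hit[, 2]]],
                            distance = d[hit], stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# z-score matrix rows (features x cells); returns scaled rows and a flag for
# zero-variance features.
zscore_rows <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  z <- (x - mu) / ifelse(s > 0, s, 1)
  list(z = z, ok = s > 0)
}

#' Correlation-based peak-to-gene links with matched-background z-scores
#'
#' For each candidate pair, r = Pearson(peak accessibility, gene expression)
#' across cells; the null is the set of r values for `n_background` peaks
#' sampled to match the focal peak's GC and mean accessibility (decile x
#' decile binning, widening to neighboring bins when short; seeded);
#' z = (r - mean(null)) / sd(null) and p = 1 - Phi(z) (one-sided upper: only
#' positive links are retained downstream). Zero-variance peaks or genes are
#' skipped with a reason.
#'
#' @param atac_norm peaks x cells normalized accessibility.
#' @param rna_norm genes x cells normalized expression (same cells).
#' @param pairs data.frame peak_id/gene_id (e.g. from [candidate_pairs()]).
#' @param peak_features data.frame peak_id, gc, mean_accessibility for all
#'   peaks usable as background.
#' @param n_background background peaks per focal peak (default 200).
#' @param seed integer seed.
#' @param link_p retention threshold (default 0.05; retained links also need
#'   z > 0).
#' @return data.frame peak_id, gene_id, distance?, pearson_r, bg_mean, bg_sd,
#'   z_score, p_value, retained, skipped_reason.
#' @export
link_peaks <- function(atac_norm, rna_norm, pairs, peak_features,
                       n_background = 200, seed = 1L, link_p = 0.05) {
  assert_that(ncol(atac_norm) == ncol(rna_norm) &&
                all(colnames(atac_norm) == colnames(rna_norm)),
              "matrices must cover the identical cell set")
  assert_that(n_background <= nrow(peak_features),
              "n_background exceeds available peaks")
  n <- ncol(atac_norm)
  za <- zscore_rows(as.matrix(atac_norm))
  zr <- zscore_rows(as.matrix(rna_norm))
  feat <- peak_features[match(rownames(atac_norm), peak_features$peak_id), ]
  bins <- paste(decile_bin(feat$gc), decile_bin(feat$mean_accessibility))
  gc_bin <- decile_bin(feat$gc); acc_bin <- decile_bin(feat$mean_accessibility)
  set.seed(as.integer(seed))
  # background pool per focal peak: same (gc, accessibility) bin, widened to
  # neighbor bins until n_background candidates exist
  sample_background <- function(focal_idx) {
    w <- 0
    repeat {
      pool <- which(abs(gc_bin - gc_bin[focal_idx]) <= w &
                    abs(acc_bin - acc_bin[focal_idx]) <= w)
      pool <- setdiff(pool, focal_idx)
      if (length(pool) >= n_background || w >= 10) break
      w <- w + 1
    }
    pool[sample.int(length(pool), min(n_background, length(pool)))]
  }
  out <- pairs
  out$pearson_r <- NA_real_; out$bg_mean <- NA_real_; out$bg_sd <- NA_real_
  out$z_score <- NA_real_; out$p_value <- NA_real_
  out$skipped_reason <- NA_character_
  # correlations per gene via one matrix product against all peak rows
  for (g in unique(pairs$gene_id)) {
    rows <- which(pairs$gene_id == g)
    gi <- match(g, rownames(rna_norm))
    if (is.na(gi) || !zr$ok[gi]) {
      out$skipped_reason[rows] <- "zero-variance or missing gene"
      next
    }
    r_all <- as.vector(za$z %*% zr$z[gi, ]) / (n - 1)
    for (i in rows) {
      pidx <- match(pairs$peak_id[i], rownames(atac_norm))
      if (is.na(pidx) || !za$ok[pidx]) {
        out$skipped_reason[i] <- "zero-variance or missing peak"
        next
      }
      bg <- sample_background(pidx)
      bg <- bg[za$ok[bg]]
      r_null <- r_all[bg]
      mu <- mean(r_null); s <- sd(r_null)
      z <- if (s > 0) (r_all[pidx] - mu) / s else 0
      out$pearson_r[i] <- r_all[pidx]
      out$bg_mean[i] <- mu; out$bg_sd[i] <- s
      out$z_score[i] <- z
      out$p_value[i] <- pnorm(z, lower.tail = FALSE)
    }
  }
  out$retained <- !is.na(out$p_value) & out$p_value < link_p & out$z_score > 0
  log_stage("link", "pairs tested: %d, retained: %d, skipped: %d",
            nrow(out), sum(out$retained), sum(!is.na(out$skipped_reason)))
  out
}

#' Subset links to a gene list
#'
#' @param links LinkResult table.
#' @param gene_list gene ids of interest.
#' @return links for those genes, ordered by (gene, p).
#' @export
links_for_genes <- function(links, gene_list) {
  out <- links[links$gene_id %in% gene_list, , drop = FALSE]
  out[order(out$gene_id, out$p_value), ]
}

#' Fraction of DEGs having at least one DA linked peak
#'
#' numerator = DEGs with >= 1 retained link whose peak is a DAP; denominator
#' = DEGs with >= 1 retained link. NA when the denominator is zero.
#'
#' @param daps DAP feature ids.
#' @param degs DEG feature ids.
#' @param links LinkResult table (retained links are used).
#' @return fraction in [0, 1], or NA.
#' @export
dap_deg_overlap <- function(daps, degs, links) {
  lk <- links[links$retained, , drop = FALSE]
  linked_degs <- intersect(degs, lk$gene_id)
  if (length(linked_degs) == 0) return(NA_real_)
  has_dap <- vapply(linked_degs, function(g)
    any(lk$peak_id[lk$gene_id == g] %in% daps), TRUE)
  mean(has_dap)
}
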