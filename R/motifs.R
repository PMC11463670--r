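#' Position frequency matrix to log-odds PWM
#'
#' pwm[b, j] = log2(((pfm[b, j] + pseudocount * bg_b) / (colsum_j +
#' pseudocount)) / bg_b); max_score = sum_j max_b pwm[b, j].
#'
#' @param pfm 4 x L non-negative count matrix (rows A, C, G, T).
#' @param pseudocount default 0.8 (split by background frequency).
#' @param background base frequencies (default uniform).
#' @return list(id-less pwm matrix, max_score, length).
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8,
                       background = c(0.25, 0.25, 0.25, 0.25)) {
  assert_that(nrow(pfm) == 4, "PFM must have 4 rows")
  cs <- colSums(pfm)
  assert_that(all(cs > 0), "PFM column with zero total")
  pwm <- log2(sweep(sweep(pfm, 1, pseudocount * background, "+"),
                    2, cs + pseudocount, "/") / background)
  rownames(pwm) <- c("A", "C", "G", "T")
  list(pwm = pwm, max_score = sum(apply(pwm, 2, max)), length = ncol(pwm))
}

# sequence string -> integer codes (A=1, C=2, G=3, T=4, N/other=5)
encode_seq <- function(s) {
  b <- strsplit(toupper(s), "")[[1]]
  code <- match(b, BASES)
  code[is.na(code)] <- 5L
  code
}

revcomp_code <- function(code) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rev(comp[code])
}

# windowed PWM scores along an encoded sequence; N contributes 0
scan_scores <- function(code, pwm) {
  L <- ncol(pwm)
  W <- length(code) - L + 1L
  if (W < 1L) return(numeric(0))
  lut <- rbind(pwm, 0)                       # 5th row: N
  sc <- numeric(W)
  for (j in seq_len(L))
    sc <- sc + lut[cbind(code[j:(j + W - 1L)], j)]
  sc
}

#' Scan sequences for motif hits on both strands
#'
#' A hit is recorded at offset o (1-based within the sequence) on either
#' strand when the window score reaches `threshold_frac * max_score`; the
#' reverse strand scans the reverse complement. Sequences shorter than the
#' motif yield no hits.
#'
#' @param sequences named character vector (names = peak ids) over
#'   {A, C, G, T, N}.
#' @param pwms named list of [pfm_to_pwm()] results (or a single one).
#' @param threshold_frac fraction of the maximum log-odds (default 0.8).
#' @return list(matrix = peaks x motifs binary, hits = data.frame peak_id,
#'   motif_id, offset, strand, score).
#' @export
scan_sequences <- function(sequences, pwms, threshold_frac = 0.8) {
  if (!is.null(pwms$pwm)) pwms <- list(motif = pwms)
  codes <- lapply(sequences, encode_seq)
  rc <- lapply(codes, revcomp_code)
  hit_rows <- list()
  mat <- matrix(0L, length(sequences), length(pwms),
                dimnames = list(names(sequences), names(pwms)))
  for (m in names(pwms)) {
    pwm <- pwms[[m]]$pwm
    thr <- threshold_frac * pwms[[m]]$max_score
    L <- ncol(pwm)
    for (i in seq_along(codes)) {
      fwd <- scan_scores(codes[[i]], pwm)
      rev_ <- scan_scores(rc[[i]], pwm)
      f_hit <- which(fwd >= thr - 1e-9)
      r_hit <- which(rev_ >= thr - 1e-9)
      if (length(f_hit) + length(r_hit) == 0) next
      mat[i, m] <- 1L
      n_code <- length(codes[[i]])
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        peak_id = names(sequences)[i], motif_id = m,
        offset = c(f_hit, n_code - L + 2L - r_hit),
        strand = rep(c("+", "-"), c(length(f_hit), length(r_hit))),
        score = c(fwd[f_hit], rev_[r_hit]), stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(peak_id = character(), motif_id = character(),
               offset = integer(), strand = character(), score = numeric())
  list(matrix = mat, hits = hits)
}

#' GC/accessibility-matched background peaks
#'
#' Samples `n` peaks without replacement, stratified so the background's
#' (GC decile x accessibility decile) composition matches the foreground's
#' (proportionally), widening to neighboring strata when a stratum is short
#' (with a warning). The background is disjoint from the foreground.
#'
#' @param foreground foreground peak ids.
#' @param peak_features data.frame peak_id, gc, mean_accessibility over all
#'   peaks.
#' @param n background size (<= available candidates).
#' @param seed integer seed.
#' @return character vector of background peak ids.
#' @export
matched_background_peaks <- function(foreground, peak_features, n, seed = 1L) {
  cand <- setdiff(peak_features$peak_id, foreground)
  assert_that(n <= length(cand), "n exceeds available candidate peaks")
  set.seed(as.integer(seed))
  gc_bin <- decile_bin(peak_features$gc)
  acc_bin <- decile_bin(peak_features$mean_accessibility)
  names(gc_bin) <- names(acc_bin) <- peak_features$peak_id
  fg_gc <- gc_bin[foreground]; fg_acc <- acc_bin[foreground]
  strata <- paste(fg_gc, fg_acc)
  want <- table(strata)
  quota <- round(want / sum(want) * n)
  # fix rounding drift
  while (sum(quota) != n) {
    j <- if (sum(quota) < n) which.max(want - quota) else which.max(quota)
    quota[j] <- quota[j] + sign(n - sum(quota))
  }
  taken <- character(0)
  for (s in names(quota)) {
    if (quota[[s]] == 0) next
    parts <- as.integer(strsplit(s, " ")[[1]])
    # GC matching is the primary criterion: widen the accessibility stratum
    # first and relax GC only as a last resort
    widen <- cbind(gc = c(rep(0:10, each = 11)), acc = rep(0:10, 11))
    widen <- widen[order(widen[, "gc"], widen[, "acc"]), ]
    pool <- character(0); w_used <- c(0, 0)
    for (r in seq_len(nrow(widen))) {
      pool <- cand[abs(gc_bin[cand] - parts[1]) <= widen[r, "gc"] &
                   abs(acc_bin[cand] - parts[2]) <= widen[r, "acc"]]
      pool <- setdiff(pool, taken)
      w_used <- widen[r, ]
      if (length(pool) >= quota[[s]]) break
    }
    if (any(w_used > 0))
      warning(sprintf("stratum %s short; widened to gc +/- %d, acc +/- %d bins",
                      s, w_used[1], w_used[2]))
    taken <- c(taken, pool[sample.int(length(pool), min(quota[[s]], length(pool)))])
  }
  taken
}

#' Motif enrichment in foreground vs background peaks
#'
#' Universe = foreground plus background; p = upper-tail hypergeometric for
#' foreground hits; fold = (fg hit rate) / (bg hit rate) with +0.5 continuity
#' on a zero background; BH across motifs.
#'
#' @param foreground,background disjoint peak id sets (foreground non-empty).
#' @param hit_matrix peaks x motifs binary matrix covering both sets.
#' @return data.frame motif_id, fg_hits, bg_hits, fold, p, fdr.
#' @export
motif_enrichment <- function(foreground, background, hit_matrix) {
  assert_that(length(foreground) > 0, "empty foreground")
  assert_that(length(intersect(foreground, background)) == 0,
              "foreground and background must be disjoint")
  fg <- hit_matrix[foreground, , drop = FALSE]
  bg <- hit_matrix[background, , drop = FALSE]
  N <- length(foreground) + length(background)
  n <- length(foreground)
  res <- data.frame(motif_id = colnames(hit_matrix),
                    fg_hits = colSums(fg), bg_hits = colSums(bg),
                    stringsAsFactors = FALSE)
  K <- res$fg_hits + res$bg_hits
  res$fold <- (res$fg_hits / n) /
    ifelse(res$bg_hits > 0, res$bg_hits / length(background),
           0.5 / length(background))
  res$p <- phyper(res$fg_hits - 1, K, N - K, n, lower.tail = FALSE)
  res$fdr <- bh_adjust(res$p)
  rownames(res) <- NULL
  res[order(res$p, res$motif_id), ]
}

#' Per-cell motif deviations (chromVAR-style)
#'
#' e_p = peak total / grand total; for motif k and cell i, o = sum of counts
#' in motif peaks, x = T_i * sum of e_p over motif peaks, raw deviation
#' y = (o - x) / x. For each of `n_iterations` background iterations every
#' motif peak is replaced by a (GC decile x accessibility decile)-matched
#' sampled peak and y recomputed; z = (y - mean(y_bg)) / sd(y_bg).
#'
#' @param atac CountMatrix of raw counts (peaks x cells).
#' @param hit_matrix peaks x motifs binary matrix over the same peaks.
#' @param peak_features data.frame peak_id, gc, mean_accessibility.
#' @param n_iterations background iterations (default 50).
#' @param seed integer seed.
#' @return list(raw motifs x cells, z motifs x cells, missing motif ids).
#' @export
chromvar_deviations <- function(atac, hit_matrix, peak_features,
                                n_iterations = 50, seed = 1L) {
  assert_that(all(rownames(atac) == rownames(hit_matrix)),
              "counts and hits must cover identical peaks")
  x <- as.matrix(atac)
  Tz <- colSums(x)
  e <- rowSums(x) / sum(x)
  feat <- peak_features[match(rownames(x), peak_features$peak_id), ]
  gc_bin <- decile_bin(feat$gc); acc_bin <- decile_bin(feat$mean_accessibility)
  bin_key <- paste(gc_bin, acc_bin)
  bin_members <- split(seq_len(nrow(x)), bin_key)
  H <- hit_matrix != 0
  dev_for <- function(peak_sets) {
    # peak_sets: list per motif of peak indices
    t(vapply(peak_sets, function(idx) {
      if (length(idx) == 0) return(rep(NA_real_, ncol(x)))
      o <- colSums(x[idx, , drop = FALSE])
      xe <- Tz * sum(e[idx])
      ifelse(xe > 0, (o - xe) / xe, NA_real_)
    }, numeric(ncol(x))))
  }
  motif_peaks <- lapply(colnames(H), function(m) which(H[, m]))
  names(motif_peaks) <- colnames(H)
  raw <- dev_for(motif_peaks)
  set.seed(as.integer(seed))
  bg_sum <- matrix(0, nrow(raw), ncol(raw))
  bg_sq <- matrix(0, nrow(raw), ncol(raw))
  for (it in seq_len(n_iterations)) {
    bg_sets <- lapply(motif_peaks, function(idx) {
      vapply(idx, function(p) {
        pool <- bin_members[[bin_key[p]]]
        pool[sample.int(length(pool), 1)]
      }, 0L)
    })
    yb <- dev_for(bg_sets)
    bg_sum <- bg_sum + yb
    bg_sq <- bg_sq + yb^2
  }
  mu <- bg_sum / n_iterations
  sdev <- sqrt(pmax(0, bg_sq / n_iterations - mu^2) *
                 n_iterations / max(1, n_iterations - 1))
  z <- (raw - mu) / ifelse(sdev > 0, sdev, NA_real_)
  dimnames(raw) <- dimnames(z) <- list(colnames(H), colnames(x))
  missing <- colnames(H)[apply(is.na(raw), 1, all)]
  list(raw = raw, z = z, missing = missing, n_iterations = n_iterations)
}
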