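test_that("PFM to PWM follows the log-odds closed forms", {
  uni <- matrix(5, 4, 6)
  p <- pfm_to_pwm(uni)
  expect_true(all(abs(p$pwm) < 1e-12))
  expect_equal(p$max_score, 0)

  # single-base columns: closed form per column
  cons <- matrix(0, 4, 3); cons[1, ] <- 7   # AAA with count 7
  p2 <- pfm_to_pwm(cons, pseudocount = 0.8)
  per_col <- log2(((7 + 0.2) / (7 + 0.8)) / 0.25)
  expect_equal(p2$max_score, 3 * per_col)

  # independent loop recomputation
  set.seed(5)
  pfm <- matrix(rpois(4 * 8, 4) + 1, 4, 8)
  p3 <- pfm_to_pwm(pfm, pseudocount = 0.8)
  brute <- matrix(0, 4, 8)
  for (b in 1:4) for (j in 1:8)
    brute[b, j] <- log2(((pfm[b, j] + 0.8 * 0.25) / (sum(pfm[, j]) + 0.8)) / 0.25)
  expect_equal(unname(p3$pwm), brute)
  expect_error(pfm_to_pwm(matrix(0, 4, 2)), "zero")
})

test_that("scanning finds consensus hits on both strands, brute-force checked", {
  pwm <- pfm_to_pwm(multiomePGC:::consensus_pfm("ACGTAC"))
  hit <- scan_sequences(c(pk = "ACGTAC"), list(m = pwm), 0.8)
  expect_equal(hit$matrix["pk", "m"], 1L)
  expect_equal(hit$hits$offset[1], 1)
  expect_equal(hit$hits$score[1], pwm$max_score)
  # all-N sequence: no hits
  expect_equal(sum(scan_sequences(c(n = strrep("N", 30)),
                                  list(m = pwm), 0.5)$matrix), 0)
  # reverse-complement-only occurrence is found on the minus strand
  rc <- scan_sequences(c(pk = "TTGTACGTTT"), list(m = pwm), 0.99)
  expect_equal(rc$hits$strand, "-")

  # random sequences vs brute-force window scoring on both strands
  set.seed(9)
  seqs <- setNames(vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""), ""),
    paste0("s", 1:30))
  got <- scan_sequences(seqs, list(m = pwm), 0.6)
  thr <- 0.6 * pwm$max_score
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  brute_hit <- vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    rcb <- rev(unname(comp[b]))
    win_score <- function(v, o) sum(vapply(1:6, function(j)
      pwm$pwm[v[o + j - 1], j], 0))
    any(vapply(1:(40 - 5), function(o)
      win_score(b, o) >= thr - 1e-9 || win_score(rcb, o) >= thr - 1e-9, TRUE))
  }, TRUE)
  expect_equal(got$matrix[, "m"] == 1, brute_hit)
})

test_that("matched backgrounds mirror the foreground composition", {
  set.seed(15)
  feats <- data.frame(peak_id = paste0("p", 1:600),
                      gc = runif(600), mean_accessibility = rexp(600))
  # foreground all in one gc decile with ample candidates
  lo <- feats$peak_id[feats$gc < quantile(feats$gc, 0.1)]
  fg <- lo[1:10]
  bg <- suppressWarnings(matched_background_peaks(fg, feats, 20, seed = 1))
  expect_length(bg, 20)
  expect_length(intersect(bg, fg), 0)
  expect_true(all(feats$gc[match(bg, feats$peak_id)] <=
                    quantile(feats$gc, 0.13)))
  # n = all candidates returns everything
  tiny <- feats[1:30, ]
  all_bg <- suppressWarnings(
    matched_background_peaks(tiny$peak_id[1:5], tiny, 25, seed = 1))
  expect_setequal(all_bg, tiny$peak_id[6:30])

  # matching beats a uniform random draw on the gc histogram, over seeds
  fg2 <- sample(feats$peak_id[order(feats$gc)][1:120], 60)  # biased foreground
  chi <- function(b) {
    f <- table(cut(feats$gc[match(fg2, feats$peak_id)], seq(0, 1, 0.1)))
    g <- table(cut(feats$gc[match(b, feats$peak_id)], seq(0, 1, 0.1)))
    sum((f / sum(f) - g / sum(g))^2)
  }
  set.seed(2)
  wins <- vapply(1:20, function(s) {
    m <- suppressWarnings(matched_background_peaks(fg2, feats, 60, seed = s))
    u <- sample(setdiff(feats$peak_id, fg2), 60)
    chi(m) < chi(u)
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("motif enrichment matches closed-form and enumerated tails", {
  mat <- matrix(0L, 100, 1, dimnames = list(paste0("p", 1:100), "m"))
  mat[1:10, 1] <- 1L
  res <- motif_enrichment(paste0("p", 1:10), paste0("p", 11:100), mat)
  expect_equal(res$p, 1 / choose(100, 10))
  # identical hit rates: no enrichment
  mat2 <- matrix(0L, 100, 1, dimnames = dimnames(mat))
  mat2[c(1:5, 11:55), 1] <- 1L
  res2 <- motif_enrichment(paste0("p", 1:10), paste0("p", 11:100), mat2)
  expect_gte(res2$p, 0.5)

  # 12-peak universe: exact combinatorial enumeration
  set.seed(20)
  ids <- paste0("u", 1:12)
  hitm <- matrix(rbinom(12, 1, 0.4), 12, 1, dimnames = list(ids, "m"))
  fg <- ids[1:5]; bg <- ids[6:12]
  res3 <- motif_enrichment(fg, bg, hitm)
  K <- sum(hitm); k <- sum(hitm[fg, ])
  enum <- sum(vapply(k:min(5, K), function(j)
    choose(K, j) * choose(12 - K, 5 - j), 0)) / choose(12, 5)
  expect_equal(res3$p, enum, tolerance = 1e-12)
  expect_error(motif_enrichment(character(), bg, hitm), "foreground")
})

test_that("chromVAR-style deviations are zero at expectation and flag activity", {
  set.seed(30)
  n_p <- 120; n_c <- 80
  ids <- paste0("p", 1:n_p)
  e_w <- rexp(n_p) + 0.2
  # counts exactly proportional to the expected accessibility profile
  depth <- sample(5:9, n_c, TRUE)
  exact <- outer(round(e_w * 50) + 1, depth)  # integer columns, exactly proportional
  cm <- count_matrix(exact, ids, paste0("c", 1:n_c), "atac")
  hits <- matrix(0L, n_p, 2, dimnames = list(ids, c("m1", "m2")))
  hits[1:20, "m1"] <- 1L; hits[51:70, "m2"] <- 1L
  feats <- data.frame(peak_id = ids, gc = runif(n_p),
                      mean_accessibility = rowMeans(exact))
  dev <- chromvar_deviations(cm, hits, feats, n_iterations = 10, seed = 1)
  expect_lt(max(abs(dev$raw), na.rm = TRUE), 1e-10)

  # raw deviation equals an independent dense-loop recomputation
  counts <- matrix(rpois(n_p * n_c, 2), n_p, n_c,
                   dimnames = list(ids, paste0("c", 1:n_c)))
  cm2 <- count_matrix(counts, ids, colnames(counts), "atac")
  dev2 <- chromvar_deviations(cm2, hits, feats, n_iterations = 5, seed = 1)
  ep <- rowSums(counts) / sum(counts)
  for (m in c("m1", "m2")) {
    idx <- which(hits[, m] == 1)
    o <- colSums(counts[idx, ]); x <- colSums(counts) * sum(ep[idx])
    expect_equal(unname(dev2$raw[m, ]), unname((o - x) / x), tolerance = 1e-10)
  }

  # planted active population: doubled counts in motif peaks push z up;
  # heterogeneous peak rates so planted peaks share accessibility bins with
  # unplanted ones
  n_p4 <- 400; n_c4 <- 100
  ids4 <- paste0("r", seq_len(n_p4))
  rates <- runif(n_p4, 1, 8)
  counts4 <- matrix(rpois(n_p4 * n_c4, rates), n_p4, n_c4,
                    dimnames = list(ids4, paste0("c", seq_len(n_c4))))
  motif_pk <- sample(which(rates > 3 & rates < 5), 30)
  hits4 <- matrix(0L, n_p4, 1, dimnames = list(ids4, "m1"))
  hits4[motif_pk, 1] <- 1L
  counts4[motif_pk, 1:50] <- counts4[motif_pk, 1:50] * 2L
  feats4 <- data.frame(peak_id = ids4, gc = runif(n_p4),
                       mean_accessibility = rowMeans(counts4))
  dev3 <- chromvar_deviations(count_matrix(counts4, ids4, colnames(counts4), "atac"),
                              hits4, feats4, n_iterations = 25, seed = 3)
  expect_gt(mean(dev3$z["m1", 1:50]), 1)
  expect_gt(mean(dev3$z["m1", 1:50]), mean(dev3$z["m1", 51:100]))
})
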