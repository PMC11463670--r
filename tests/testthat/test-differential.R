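test_that("Wilcoxon p equals independent oracles for small groups", {
  # {1,2,3} vs {4,5,6}: most extreme of C(6,3)=20 orderings, two-sided
  expect_equal(wilcoxon_test(1:3, 4:6), 2 / 20)
  expect_equal(wilcoxon_test(c(2, 2, 2), c(2, 2, 2)), 1)

  # tie-free cases agree with the reference exact distribution
  set.seed(42)
  for (i in 1:10) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(wilcoxon_test(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # heavy ties: agree with a Monte-Carlo permutation oracle
  set.seed(43)
  for (i in 1:5) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- sample(1:3, n1, TRUE); y <- sample(1:4, n2, TRUE)
    if (length(unique(c(x, y))) == 1) next
    expect_equal(wilcoxon_test(x, y), mc_wilcox_p(x, y), tolerance = 0.02)
  }
})

test_that("normal approximation tracks the exact p at the crossover size", {
  set.seed(44)
  diffs <- replicate(20, {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    r <- rank(c(x, y))
    w <- sum(r[1:8])
    approx_p <- multiomePGC:::wilcoxon_normal_p(w, r, 8, 8)
    abs(approx_p - wilcoxon_test(x, y))
  })
  expect_lt(median(diffs), 1e-2)
  expect_lt(max(diffs), 5e-2)
})

test_that("log2 fold change has its closed forms and antisymmetry", {
  expect_equal(log2_fold_change(3, 3), 0)
  expect_equal(log2_fold_change(3, 1, pseudocount = 1), 1)
  set.seed(1)
  a <- runif(20, 0, 5); b <- runif(20, 0, 5)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
})

test_that("BH adjustment equals the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(6)
  p <- runif(200)
  expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  o <- sample(200)
  expect_equal(bh_adjust(p[o]), bh_adjust(p)[o])
})

test_that("find_markers applies pre-filters and ranks planted effects first", {
  set.seed(10)
  n_c <- 80
  cells <- paste0("c", seq_len(2 * n_c))
  g1 <- cells[1:n_c]; g2 <- cells[-(1:n_c)]
  counts <- matrix(rpois(50 * 2 * n_c, 2), 50, 2 * n_c,
                   dimnames = list(paste0("g", 1:50), cells))
  counts["g1", g1] <- rpois(n_c, 8)            # planted marker
  counts["g2", ] <- rbinom(2 * n_c, 1, 0.2)    # expressed in ~20 percent
  norm <- lognormalize(counts)
  res <- find_markers(norm, g1, g2, min_pct = 0.25, logfc_threshold = 0.25)
  expect_equal(res$feature[1], "g1")
  expect_true(res$significant[1])
  expect_false("g2" %in% res$feature)          # min.pct rule: not tested
  expect_true(all(res$fdr >= res$p - 1e-12 | res$fdr <= 1))

  # permuted labels lose the planted signal
  set.seed(11)
  perm <- sample(cells)
  resp <- find_markers(norm, perm[1:n_c], perm[-(1:n_c)],
                       min_pct = 0, logfc_threshold = 0)
  expect_lte(mean(resp$fdr < 0.05), 0.05)
  expect_error(find_markers(norm, g1, g1, 0, 0), "disjoint")
})

test_that("one-vs-rest markers find a planted cluster gene and permute cleanly", {
  set.seed(14)
  cells <- paste0("c", 1:90)
  counts <- matrix(rpois(30 * 90, 2), 30, 90,
                   dimnames = list(paste0("g", 1:30), cells))
  labels <- setNames(rep(0:2, each = 30), cells)
  counts["g5", labels == 1] <- rpois(30, 15)
  norm <- lognormalize(counts)
  all_m <- find_all_markers(norm, labels, min_pct = 0.1, logfc_threshold = 0.1)
  up1 <- all_m[["1"]]
  expect_equal(up1$feature[up1$direction == "up"][1], "g5")
  # renaming clusters permutes output blocks only
  relab <- setNames(c(2L, 0L, 1L)[labels + 1L], cells)
  all_m2 <- find_all_markers(norm, relab, min_pct = 0.1, logfc_threshold = 0.1)
  expect_equal(all_m[["1"]], all_m2[["0"]])
})

test_that("peak annotation follows promoter > exon > intron > distal precedence", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(10000, 50000), end = c(20000, 60000),
                      strand = c("+", "-"),
                      is_mitochondrial = FALSE, is_chrY = FALSE)
  genes <- multiomePGC:::validate_gene_model(genes)
  pk <- data.frame(chrom = "chr1",
                   start = c(9900, 15000, 90000, 59000),
                   end = c(10100, 15200, 90200, 59500))
  pk$peak_id <- paste0("p", 1:4)
  ann <- annotate_peaks(pk, genes)
  expect_equal(ann$category, c("promoter", "intron", "distal_intergenic",
                               "promoter"))  # p4 spans gB's minus-strand TSS

  # random peaks vs brute-force with the stated precedence
  set.seed(23)
  rp <- data.frame(chrom = "chr1", start = sample.int(1e5, 300))
  rp$end <- rp$start + 150
  rp$peak_id <- paste0("r", 1:300)
  ex <- data.frame(chrom = "chr1", start = 12000, end = 13000)
  ann2 <- annotate_peaks(rp, genes, exons = ex)
  brute <- sapply(seq_len(300), function(i) {
    s <- rp$start[i]; e <- rp$end[i]
    ov <- function(a, b) s <= b & a < e          # 0-based half-open vs closed window
    prom <- any(ov(genes$tss - 3000, genes$tss + 3000))
    if (prom) return("promoter")
    if (ov(ex$start, ex$end - 1)) return("exon")
    if (any(ov(genes$start, genes$end - 1))) return("intron")
    "distal_intergenic"
  })
  expect_equal(ann2$category, unname(brute))
})

test_that("gene-set over-representation has exact hypergeometric tails", {
  uni <- paste0("g", 1:20)
  hits <- paste0("g", 1:5)
  sets <- list(all5 = paste0("g", 1:5), none = paste0("g", 16:20))
  res <- geneset_ora(hits, uni, sets)
  expect_equal(res$p[res$set == "all5"], 1 / choose(20, 5))
  expect_equal(res$overlap[res$set == "none"], 0)
  # hits = set = universe -> p = 1
  res2 <- geneset_ora(uni, uni, list(s = uni))
  expect_equal(res2$p, 1)
  # null uniformity: p approximately uniform under random sets
  set.seed(3)
  uni2 <- paste0("u", 1:500)
  hits2 <- sample(uni2, 50)
  sets2 <- lapply(1:200, function(i) sample(uni2, 40))
  names(sets2) <- paste0("s", 1:200)
  p <- geneset_ora(hits2, uni2, sets2)$p
  # discrete upper-tail p-values are valid (super-uniform) under the null
  expect_lte(mean(p < 0.05), 0.07)
  expect_gte(mean(p > 0.5), 0.3)
  expect_error(geneset_ora(hits, character(), sets), "universe")
})
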