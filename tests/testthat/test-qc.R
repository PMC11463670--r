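mk_genes <- function(ids, mito = character(), chrom = "chr1") {
  data.frame(gene_id = ids, chrom = chrom, start = 100, end = 5000,
             strand = "+", tss = 100,
             is_mitochondrial = ids %in% mito, is_chrY = FALSE,
             stringsAsFactors = FALSE)
}

test_that("RNA QC metrics match hand arithmetic and a dense-loop oracle", {
  genes <- mk_genes(c("mt1", "g1"), mito = "mt1")
  m <- count_matrix(matrix(c(25, 75, 0, 0), 2, 2,
                           dimnames = list(c("mt1", "g1"), c("a", "b"))),
                    c("mt1", "g1"), c("a", "b"))
  qc <- compute_rna_qc(m, genes)
  expect_equal(qc$pct_mito, c(25, 0))
  expect_equal(qc$n_count_rna, c(100, 0))

  set.seed(5)
  ids <- sprintf("g%02d", 1:20)
  mito <- sample(ids, 4)
  r <- matrix(rpois(20 * 30, 2), 20, 30, dimnames = list(ids, sprintf("c%02d", 1:30)))
  qc2 <- compute_rna_qc(count_matrix(r, ids, colnames(r)), mk_genes(ids, mito))
  brute <- sapply(seq_len(30), function(j) {
    tot <- sum(r[, j]); mt <- sum(r[mito, j])
    c(tot, if (tot == 0) 0 else 100 * mt / tot)
  })
  expect_equal(qc2$n_count_rna, brute[1, ])
  expect_equal(qc2$pct_mito, brute[2, ])

  expect_error(compute_rna_qc(m, mk_genes("mt1", "mt1")), "absent")
})

test_that("nucleosome signal is the mono/sub fragment ratio", {
  fr <- data.frame(chrom = "chr1",
                   start = rep(0, 15),
                   end = c(rep(100, 10), rep(200, 5)),
                   barcode = "cellA", count = 1L)
  expect_equal(unname(compute_nucleosome_signal(fr, "cellA")), 0.5)
  expect_equal(unname(compute_nucleosome_signal(fr[0, ], "cellA")), 0)

  # planted mixture vs direct count
  set.seed(9)
  len <- c(sample(30:146, 200, TRUE), sample(147:294, 120, TRUE),
           sample(295:400, 30, TRUE))
  fr2 <- data.frame(chrom = "chr1", start = 0, end = len,
                    barcode = sample(c("x", "y"), 350, TRUE), count = 1L)
  ns <- compute_nucleosome_signal(fr2, c("x", "y"))
  for (b in c("x", "y")) {
    l <- fr2$end[fr2$barcode == b]
    expect_equal(unname(ns[b]), sum(l >= 147 & l <= 294) / max(1, sum(l < 147)))
  }
})

test_that("TSS enrichment is 1 for flat coverage and large for pure pileup", {
  genes <- mk_genes("g1")
  genes$tss <- 5000
  # fragments tiling uniformly across the whole window
  fr <- data.frame(chrom = "chr1", start = seq(2000, 8000, by = 50),
                   end = seq(2000, 8000, by = 50) + 50,
                   barcode = "u", count = 1L)
  fold <- compute_tss_enrichment(fr, genes, "u")
  expect_equal(unname(fold), 1, tolerance = 0.1)

  # fragments only at the TSS, none in flanks -> sentinel
  fr2 <- data.frame(chrom = "chr1", start = 4950, end = 5050,
                    barcode = "p", count = 1L)
  expect_equal(unname(compute_tss_enrichment(fr2, genes, "p")), 1e6)
  expect_error(compute_tss_enrichment(fr, genes[0, ], "u"), "empty")
})

test_that("cell filtering applies strict inequalities rule by rule", {
  cfg <- pipeline_config()
  mk <- function(rna, mito, atac, ns, tss)
    data.frame(cell_id = "c", n_count_rna = rna, pct_mito = mito,
               n_count_atac = atac, nucleosome_signal = ns, tss_enrichment = tss)
  # boundary value excluded (strict >)
  expect_length(filter_cells(mk(1000, 10, 5000, 1, 2), cfg)$retained, 0)
  expect_equal(filter_cells(mk(1500, 10, 5000, 1, 2), cfg)$retained, "c")
  expect_length(filter_cells(mk(1500, 25, 5000, 1, 2), cfg)$retained, 0)
  expect_length(filter_cells(mk(1500, 10, 100000, 1, 2), cfg)$retained, 0)

  # random metrics vs independent row-by-row evaluation
  set.seed(3)
  n <- 300
  m <- data.frame(cell_id = sprintf("c%03d", 1:n),
                  n_count_rna = runif(n, 0, 3e4),
                  pct_mito = runif(n, 0, 40),
                  n_count_atac = runif(n, 0, 1.2e5),
                  nucleosome_signal = runif(n, 0, 3),
                  tss_enrichment = runif(n, 0, 4))
  got <- filter_cells(m, cfg)$retained
  want <- m$cell_id[sapply(seq_len(n), function(i)
    m$n_count_rna[i] > 1000 && m$n_count_rna[i] < 25000 &&
      m$pct_mito[i] < 25 && m$n_count_atac[i] > 1000 &&
      m$n_count_atac[i] < 1e5 && m$nucleosome_signal[i] < 2 &&
      m$tss_enrichment[i] > 1)]
  expect_identical(got, want)
})

test_that("peak filtering enforces strict width bounds, chroms and blacklist", {
  cfg <- pipeline_config()
  pk <- data.frame(chrom = c("chr1", "chr1", "chrUn_random", "chr1"),
                   start = c(0, 0, 0, 0), end = c(20, 100, 100, 10000))
  pk$peak_id <- paste0(pk$chrom, ":", pk$start, "-", pk$end)
  kept <- filter_peaks(pk, c("chr1"), config = cfg)
  expect_equal(kept$peak_id, "chr1:0-100")   # width 20 and 10000 are strict-out

  set.seed(21)
  n <- 400
  rp <- data.frame(chrom = "chr1", start = sample.int(1e5, n))
  rp$end <- rp$start + sample(30:200, n, TRUE)
  rp$peak_id <- paste0("p", 1:n)
  bl <- data.frame(chrom = "chr1", start = c(2e4, 6e4), end = c(3e4, 6.5e4))
  kept2 <- filter_peaks(rp, "chr1", bl, cfg)
  overlap <- sapply(seq_len(n), function(i)
    any(rp$start[i] < bl$end & bl$start < rp$end[i]))
  expect_identical(kept2$peak_id, rp$peak_id[!overlap])
})

test_that("marker-count triage implements the printed raw-count rules", {
  mks <- unique(unlist(default_markers()))
  base <- matrix(0, length(mks), 4,
                 dimnames = list(mks, c("pgc", "dbl", "supp", "wt1lo")))
  base["Ddx4", "pgc"] <- 5
  base["Ddx4", "dbl"] <- 5; base["Foxl2", "dbl"] <- 1
  base["Wt1", "supp"] <- 3
  base["Wt1", "wt1lo"] <- 1
  calls <- call_cell_types(count_matrix(base, mks, colnames(base)))
  expect_equal(calls$label[calls$cell_id == "pgc"], "PGC")
  expect_equal(calls$label[calls$cell_id == "dbl"], "excluded")  # doublet rule
  expect_equal(calls$label[calls$cell_id == "supp"], "supporting")
  expect_equal(calls$label[calls$cell_id == "wt1lo"], "other") # needs Wt1 > 1

  expect_error(call_cell_types(count_matrix(base[-1, ], mks[-1],
                                            colnames(base))), "Ddx4")
})

test_that("cross-population doublets fail the triage on default synthetic data", {
  sim <- small_sim()
  truth <- sim$truth$cells
  calls <- call_cell_types(sim$rna)
  dbl <- merge(calls, truth[truth$doublet, ], by = "cell_id")
  # a doublet must not be retained as PGC or supporting
  expect_gte(mean(!dbl$label %in% c("PGC", "supporting")), 0.9)
  # good singlets survive the QC thresholds
  qc <- compute_rna_qc(sim$rna, sim$genes)
  ns <- compute_nucleosome_signal(sim$fragments, colnames(sim$rna))
  tss <- compute_tss_enrichment(sim$fragments, sim$genes, colnames(sim$rna))
  metrics <- data.frame(qc, n_count_atac = as.numeric(Matrix::colSums(sim$atac)),
                        nucleosome_signal = unname(ns),
                        tss_enrichment = unname(tss))
  kept <- filter_cells(metrics)$retained
  singlets <- truth$cell_id[!truth$doublet]
  expect_gte(mean(singlets %in% kept), 0.95)
})

test_that("mito feature removal preserves columns and zeroes pct_mito", {
  ids <- c(sprintf("mt-%d", 1:3), sprintf("g%d", 1:7))
  genes <- mk_genes(ids, mito = ids[1:3])
  m <- count_matrix(matrix(rpois(10 * 5, 2), 10, 5,
                           dimnames = list(ids, paste0("c", 1:5))), ids,
                    paste0("c", 1:5))
  out <- drop_mito_features(m, genes)
  expect_equal(nrow(out), 7)
  expect_identical(colnames(out), colnames(m))
  requal <- compute_rna_qc(out, genes[genes$gene_id %in% rownames(out), ])
  expect_true(all(requal$pct_mito == 0))
  # no mito genes -> identity
  g2 <- mk_genes(ids)
  expect_identical(drop_mito_features(m, g2), m)
})
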