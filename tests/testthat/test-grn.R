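mk_grn_fixture <- function() {
  sex_de <- data.frame(feature = c("tfA", "tfB", "tfC"),
                       log2fc = c(1.2, 0.8, 0.05), fdr = c(0.001, 0.01, 0.5),
                       stringsAsFactors = FALSE)
  germ_de <- data.frame(feature = c("tfA", "tfB", "tfC"),
                        log2fc = c(2, -1, 2), fdr = c(0.001, 0.001, 0.001),
                        stringsAsFactors = FALSE)
  enrichment <- data.frame(motif_id = c("mA", "mB", "mC"),
                           p = c(0.001, 0.002, 0.6), fdr = c(0.003, 0.003, 0.6),
                           stringsAsFactors = FALSE)
  z <- matrix(c(2, 2, 2, 1, 1, 1, -1, -1, -1), 3, 3, byrow = TRUE,
              dimnames = list(c("mA", "mB", "mC"), paste0("c", 1:3)))
  list(sex_de = sex_de, germ_de = germ_de, enrichment = enrichment,
       deviations = list(z = z),
       tf2motif = c(tfA = "mA", tfB = "mB", tfC = "mC"))
}

test_that("TF triage is the conjunction of the four criteria", {
  fx <- mk_grn_fixture()
  tri <- triage_tfs(fx$sex_de, fx$germ_de, fx$enrichment, fx$deviations,
                    fx$tf2motif, focal_cells = paste0("c", 1:3))
  expect_equal(tri$passes_all[tri$tf == "tfA"], TRUE)
  # tfB fails only germline enrichment (negative direction)
  rB <- tri[tri$tf == "tfB", ]
  expect_false(rB$passes_all)
  expect_true(rB$is_de_between_sexes && rB$motif_enriched)
  expect_match(rB$reason, "germline")
  # tfC fails sex-DE, enrichment and activity
  rC <- tri[tri$tf == "tfC", ]
  expect_false(rC$passes_all)
  expect_match(rC$reason, "not sex-DE")
  expect_equal(tri$passes_all, tri$is_de_between_sexes &
                 tri$is_germline_enriched & tri$motif_enriched &
                 (tri$mean_motif_activity_z > 0))
  # unmapped motif is skipped with a warning
  expect_warning(
    triage_tfs(fx$sex_de, fx$germ_de, fx$enrichment[-1, ], fx$deviations,
               fx$tf2motif, paste0("c", 1:3)), "tfA")
})

test_that("target assignment collapses duplicates and computes coverage", {
  cand <- data.frame(tf = "tfA", motif_id = "mA", passes_all = TRUE,
                     stringsAsFactors = FALSE)
  links <- data.frame(peak_id = c("p1", "p2", "p2", "p3"),
                      gene_id = c("g1", "g1", "g2", "g3"),
                      p_value = c(0.01, 0.001, 0.02, 0.03),
                      z_score = c(2, 3, 2, 2),
                      retained = c(TRUE, TRUE, TRUE, FALSE))
  hits <- data.frame(peak_id = c("p1", "p2"), motif_id = "mA",
                     offset = c(10L, 20L), strand = "+")
  net <- assign_targets(cand, links, hits, degs = c("g1", "g2", "g3"))
  # g1 via best-p peak p2; g2 via p2; g3's link not retained
  expect_setequal(net$edges$target, c("g1", "g2"))
  expect_equal(net$edges$peak_id[net$edges$target == "g1"], "p2")
  expect_equal(net$coverage$denominator, 2)   # g1, g2 have retained links
  expect_equal(net$coverage$coverage, 1)
  # empty candidate set -> empty network
  net0 <- assign_targets(cand[0, ], links, hits, c("g1", "g2"))
  expect_equal(nrow(net0$edges), 0)
})

test_that("cross-regulation sees motifs in linked peaks and promoters", {
  genes <- data.frame(gene_id = c("tfA", "tfB"), chrom = "chr1",
                      start = c(10000, 200000), end = c(15000, 205000),
                      strand = "+", is_mitochondrial = FALSE, is_chrY = FALSE)
  genes <- multiomePGC:::validate_gene_model(genes)
  peaks <- data.frame(chrom = "chr1", start = c(199000, 50000),
                      end = c(199500, 50500),
                      peak_id = c("promB", "elseP"))
  cand <- data.frame(tf = c("tfA", "tfB"), motif_id = c("mA", "mB"),
                     passes_all = TRUE, stringsAsFactors = FALSE)
  hits <- data.frame(peak_id = "promB", motif_id = "mA",
                     offset = 5L, strand = "+")
  links <- data.frame(peak_id = "elseP", gene_id = "tfA", p_value = 0.01,
                      z_score = 2, retained = TRUE)
  inc <- cross_regulation(cand, links, hits, genes, peaks)
  expect_equal(inc["tfA", "tfB"], 1L)     # mA hit in tfB's promoter peak
  expect_equal(inc["tfB", "tfA"], 0L)
  expect_equal(sum(inc), 1L)
  # no motifs anywhere -> zero matrix
  inc0 <- cross_regulation(cand, links, hits[0, ], genes, peaks)
  expect_true(all(inc0 == 0))
})

test_that("network summary percentages equal brute-force set arithmetic", {
  net <- list(edges = data.frame(
    tf = c("tfA", "tfA", "tfB"), target = c("g1", "g2", "g3"),
    peak_id = "p", motif_offset = 1L, link_z = 2, link_p = 0.01))
  links <- data.frame(peak_id = paste0("q", 1:4),
                      gene_id = c("g1", "g2", "g3", "g4"),
                      p_value = 0.01, z_score = 2, retained = TRUE)
  s <- network_summary(net, degs = c("g1", "g2", "g3", "g4"), links)
  expect_equal(s$per_tf$percent[s$per_tf$tf == "tfA"], 50)
  expect_equal(s$per_tf$percent[s$per_tf$tf == "tfB"], 25)
  expect_equal(s$overlaps["tfA", "tfB"], 0L)
  expect_equal(s$overlaps["tfA", "tfA"], 2L)
})

test_that("the planted regulatory network is recovered from synthetic data", {
  run <- default_grn_run()
  edges <- run$net$edges
  te <- run$sim$truth$tf_edges
  pred <- paste(edges$tf, edges$target)
  tru <- paste(te$tf, te$target)
  expect_gte(mean(pred %in% tru), 0.7)
  expect_gte(mean(tru %in% pred), 0.7)
  # shuffled motif-hit assignments collapse recovery to chance
  hits_shuf <- run$hits
  set.seed(99)
  hits_shuf$peak_id <- sample(run$all_peaks, nrow(hits_shuf), replace = TRUE)
  net_shuf <- assign_targets(run$cand, run$links, hits_shuf, run$degs)
  if (nrow(net_shuf$edges) > 0) {
    prec <- mean(paste(net_shuf$edges$tf, net_shuf$edges$target) %in% tru)
    expect_lte(prec, 0.25)
  } else succeed()
})
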