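test_that("log-normalization matches its closed form element-wise", {
  m <- matrix(c(0, 10, 0, 0), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  out <- lognormalize(m, scale = 1e4)
  expect_equal(out["g1", "a"], 0)
  expect_equal(out["g2", "a"], log(1 + 1e4))   # single expressed gene
  expect_true(all(out[, "b"] == 0))            # all-zero cell stays zero

  set.seed(4)
  r <- matrix(rpois(30 * 8, 3), 30, 8, dimnames = list(paste0("g", 1:30),
                                                       paste0("c", 1:8)))
  got <- lognormalize(r)
  tot <- colSums(r)
  for (j in 1:8) for (i in c(1, 15, 30))
    expect_equal(got[i, j], log(1 + r[i, j] * 1e4 / unname(tot[j])))
})

test_that("PCA recovers a planted variance direction with ordered components", {
  set.seed(8)
  n_g <- 60; n_c <- 120
  dir_ <- rnorm(n_g)
  x <- matrix(rnorm(n_g * n_c, sd = 0.1), n_g, n_c) +
    outer(dir_, rnorm(n_c, sd = 3))
  dimnames(x) <- list(paste0("g", 1:n_g), paste0("c", 1:n_c))
  p <- pca_reduce(x, n_hvg = n_g, n_comp = 10)
  # component 1 aligns with the planted direction after per-gene unit scaling
  eff <- dir_ / sqrt(0.1^2 + 9 * dir_^2)
  eff <- eff / sqrt(sum(eff^2))
  expect_gt(abs(sum(p$loadings[paste0("g", 1:n_g), 1] * eff)), 0.99)
  expect_true(all(diff(p$sdev) <= 1e-8))
  # duplicated cells get identical embeddings
  x2 <- cbind(x, dup = x[, 1])
  colnames(x2) <- c(colnames(x), "dup")
  p2 <- pca_reduce(x2, n_hvg = n_g, n_comp = 5)
  expect_equal(unname(p2$embedding["dup", ]), unname(p2$embedding["c1", ]),
               tolerance = 1e-8)
  expect_warning(pca_reduce(x[, 1:5], n_hvg = 20, n_comp = 10), "reduced")
})

test_that("LSI component 1 tracks sequencing depth on synthetic ATAC", {
  sim <- small_sim()
  lsi <- tfidf_lsi(sim$atac, n_comp = 20)
  expect_gt(abs(lsi$depth_cor), 0.8)
  expect_true(lsi$depth_component)
  # all-equal cells: no variance beyond component 1
  m <- matrix(2, 50, 30, dimnames = list(paste0("p", 1:50), paste0("c", 1:30)))
  lsi2 <- tfidf_lsi(count_matrix(m, rownames(m), colnames(m), "atac"), n_comp = 5)
  expect_lt(max(abs(lsi2$d[-1])), 1e-6 * lsi2$d[1])
})

test_that("SNN clustering separates planted blobs and is seeded", {
  set.seed(77)
  blob <- function(center, n) sweep(matrix(rnorm(n * 2, sd = 1), n, 2), 2,
                                    center, "+")
  coords <- rbind(blob(c(0, 0), 60), blob(c(20, 0), 60))
  rownames(coords) <- paste0("c", 1:120)
  cl <- snn_cluster(coords, k = 15, resolution = 0.3, seed = 5)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(length(unique(cl$labels[1:60])), 1)
  expect_equal(length(unique(cl$labels[61:120])), 1)
  expect_true(all(sort(unique(cl$labels)) == c(0, 1)))
  # resolution -> 0 collapses a connected graph to one cluster
  conn <- matrix(rnorm(240), 120, 2, dimnames = list(paste0("c", 1:120), NULL))
  cl0 <- snn_cluster(conn, k = 15, resolution = 1e-4, seed = 5)
  expect_equal(length(unique(cl0$labels)), 1)
  # determinism
  expect_identical(cl$labels, snn_cluster(coords, k = 15, resolution = 0.3,
                                          seed = 5)$labels)
  expect_error(snn_cluster(coords, k = 200, seed = 1), "k must be smaller")
})

test_that("joint neighbor weights are symmetric, normalized, and informative", {
  set.seed(12)
  n <- 150
  lat <- matrix(rnorm(n * 5), n, 5, dimnames = list(paste0("c", 1:n), NULL))
  w_same <- weighted_joint_neighbors(lat, lat, k = 15)$weights
  expect_true(all(abs(w_same$w_rna - 0.5) < 0.05))
  expect_true(all(abs(w_same$w_rna + w_same$w_atac - 1) < 1e-12))

  # structured RNA vs pure-noise ATAC: RNA gets up-weighted
  structured <- rbind(matrix(rnorm(75 * 5), 75, 5),
                      matrix(rnorm(75 * 5, mean = 6), 75, 5))
  rownames(structured) <- paste0("c", 1:n)
  noise <- matrix(rnorm(n * 5), n, 5, dimnames = dimnames(structured))
  w <- weighted_joint_neighbors(structured, noise, k = 15)$weights
  expect_gt(median(w$w_rna), 0.7)
})

test_that("MST pseudotime orders collinear clusters and finds Y branches", {
  set.seed(19)
  mk_blob <- function(cx, n = 50) cbind(rnorm(n, cx, 0.3), rnorm(n, 0, 0.3))
  coords <- rbind(mk_blob(0), mk_blob(5), mk_blob(10))
  rownames(coords) <- paste0("c", 1:150)
  cl <- setNames(rep(0:2, each = 50), rownames(coords))
  pt <- mst_pseudotime(coords, cl, root_cells = paste0("c", 1:50))
  expect_equal(pt$root_cluster, 0)
  # ordering matches geometric order for nearly all cells
  ord_ok <- mean(outer(pt$pseudotime[51:100], pt$pseudotime[1:50], ">")) > 0.95 &&
    mean(outer(pt$pseudotime[101:150], pt$pseudotime[51:100], ">")) > 0.95
  expect_true(ord_ok)
  # root cluster has minimal mean pseudotime
  means <- tapply(pt$pseudotime, cl, mean)
  expect_equal(names(which.min(means)), "0")
  expect_length(pt$branch_nodes, 0)
  expect_equal(sort(pt$terminal_nodes), 2)

  # Y-shaped topology: one branch point, two non-root terminal states
  coordsY <- rbind(mk_blob(0), mk_blob(5),
                   cbind(rnorm(50, 9, 0.3), rnorm(50, 3, 0.3)),
                   cbind(rnorm(50, 9, 0.3), rnorm(50, -3, 0.3)))
  rownames(coordsY) <- paste0("c", 1:200)
  clY <- setNames(rep(0:3, each = 50), rownames(coordsY))
  ptY <- mst_pseudotime(coordsY, clY, root_cells = paste0("c", 1:50))
  expect_length(ptY$branch_nodes, 1)
  expect_equal(ptY$branch_nodes, 1)
  expect_length(ptY$terminal_nodes, 2)
  expect_true(all(ptY$pseudotime >= 0))
})

test_that("clusters recover the planted population structure", {
  sim <- small_sim()
  norm <- lognormalize(sim$rna)
  p <- pca_reduce(norm, n_hvg = 500, n_comp = 18)
  cl <- snn_cluster(p, dims = 1:18, k = 15, resolution = 0.3, seed = 3)
  truth <- sim$truth$cells
  singlets <- truth$cell_id[!truth$doublet]
  pop <- truth$population[match(singlets, truth$cell_id)]
  lab <- cl$labels[singlets]
  maj <- tapply(pop, lab, function(x) names(which.max(table(x))))
  mapped <- unname(maj[as.character(lab)])
  expect_gte(ari_index(mapped, pop), 0.8)
})
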