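#' Log-normalize counts
#'
#' x' = ln(1 + count * scale / cell_total), columns with zero total stay
#' all-zero.
#'
#' @param counts CountMatrix or matrix (features x cells).
#' @param scale scale factor (default 1e4).
#' @return dense numeric matrix of the same shape.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  x <- as.matrix(counts)
  totals <- colSums(x)
  out <- log1p(sweep(x, 2, pmax(totals, 1), "/") * scale)
  dimnames(out) <- dimnames(x)
  out
}

#' PCA on highly variable genes
#'
#' Top-variance genes are selected, centered and unit-scaled (values clipped
#' at +/- 10), and the cells are projected onto the leading principal
#' components. Components are ordered by decreasing explained variance; the
#' sign convention makes the largest-magnitude gene loading positive.
#'
#' @param normalized genes x cells normalized matrix.
#' @param n_hvg number of highly variable genes (default 2000).
#' @param n_comp number of components (default 50; reduced with a warning
#'   when it reaches the matrix rank).
#' @return list(embedding cells x comp, loadings, sdev, hvg, modality).
#' @export
pca_reduce <- function(normalized, n_hvg = 2000, n_comp = 50) {
  x <- as.matrix(normalized)
  v <- apply(x, 1, var)
  hvg <- names(sort(v, decreasing = TRUE))[seq_len(min(n_hvg, sum(v > 0)))]
  xs <- t(scale(t(x[hvg, , drop = FALSE])))
  xs[xs > 10] <- 10; xs[xs < -10] <- -10
  xs[is.na(xs)] <- 0
  max_comp <- min(dim(xs)) - 1L
  if (n_comp > max_comp) {
    warning(sprintf("n_comp reduced from %d to %d (rank limit)", n_comp, max_comp))
    n_comp <- max_comp
  }
  # cells x genes
  y <- t(xs)
  cp <- crossprod(y)                       # genes x genes
  eig <- eigen(cp, symmetric = TRUE)
  keep <- seq_len(n_comp)
  load <- eig$vectors[, keep, drop = FALSE]
  emb <- y %*% load
  # sign convention: largest-magnitude loading positive
  for (j in keep) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; emb[, j] <- -emb[, j] }
  }
  rownames(load) <- hvg
  rownames(emb) <- colnames(x)
  colnames(emb) <- colnames(load) <- paste0("PC", keep)
  list(embedding = emb, loadings = load,
       sdev = sqrt(pmax(eig$values[keep], 0) / max(1, ncol(x) - 1)),
       hvg = hvg, modality = "rna")
}

#' TF-IDF / LSI reduction for ATAC counts
#'
#' TF = count / cell_total; IDF = n_cells / peak detection count; the
#' transform ln(1 + TF * IDF * 1e4) is decomposed by truncated SVD. Component
#' 1 is flagged as a depth component when |Pearson r| with log cell depth
#' exceeds 0.7, so downstream defaults use components 2..n.
#'
#' @param atac CountMatrix (peaks x cells).
#' @param n_comp number of components (default 30).
#' @return list(embedding, loadings, d, depth_component, modality).
#' @export
tfidf_lsi <- function(atac, n_comp = 30) {
  x <- as.matrix(atac)
  totals <- colSums(x)
  det <- rowSums(x > 0)
  if (any(det == 0)) {
    warning(sprintf("%d peak(s) with zero detections dropped from LSI", sum(det == 0)))
    x <- x[det > 0, , drop = FALSE]
    det <- det[det > 0]
  }
  tf <- sweep(x, 2, pmax(totals, 1), "/")
  idf <- ncol(x) / det
  z <- log1p(tf * idf * 1e4)
  n_comp <- min(n_comp, min(dim(z)) - 1L)
  cp <- crossprod(z)                       # cells x cells
  eig <- eigen(cp, symmetric = TRUE)
  keep <- seq_len(n_comp)
  d <- sqrt(pmax(eig$values[keep], 0))
  v <- eig$vectors[, keep, drop = FALSE]
  emb <- sweep(v, 2, d, "*")               # cells x comp (V D)
  u <- z %*% sweep(v, 2, pmax(d, 1e-12), "/")
  for (j in keep) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) { u[, j] <- -u[, j]; emb[, j] <- -emb[, j] }
  }
  rownames(emb) <- colnames(x)
  colnames(emb) <- paste0("LSI", keep)
  depth_cor <- suppressWarnings(cor(emb[, 1], log1p(totals)))
  list(embedding = emb, loadings = u, d = d,
       depth_component = isTRUE(abs(depth_cor) > 0.7),
       depth_cor = depth_cor, modality = "atac")
}

# k nearest neighbors (Euclidean) from a coordinate matrix; no self-neighbors.
knn_indices <- function(coords, k) {
  n <- nrow(coords)
  assert_that(k < n, "k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  idx <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  dist_k <- t(vapply(seq_len(n), function(i) d[i, idx[i, ]], numeric(k)))
  list(idx = idx, dist = dist_k, d = d)
}

# Shared-nearest-neighbor Jaccard graph from a kNN index matrix.
snn_graph <- function(idx) {
  n <- nrow(idx); k <- ncol(idx)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  shared <- as(shared, "TsparseMatrix")
  i <- shared@i + 1L; j <- shared@j + 1L; s <- shared@x
  keep <- i < j & s > 0
  jac <- s[keep] / (2 * k - s[keep])
  igraph::graph_from_data_frame(
    data.frame(from = i[keep], to = j[keep], weight = jac),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}

#' SNN graph clustering
#'
#' kNN (Euclidean in the latent space) -> shared-nearest-neighbor Jaccard
#' graph -> seeded modularity optimization with resolution gamma
#' (RB-configuration null); labels are relabeled by decreasing cluster size,
#' starting at 0.
#'
#' @param latent list from [pca_reduce()] / [tfidf_lsi()] or a matrix.
#' @param dims component indices to use.
#' @param k neighbors (default 20).
#' @param resolution modularity resolution (default 0.3).
#' @param seed integer seed.
#' @return list(labels 0-based integer per cell, modularity, resolution, k).
#' @export
snn_cluster <- function(latent, dims = NULL, k = 20, resolution = 0.3, seed = 1L) {
  coords <- if (is.list(latent)) latent$embedding else latent
  if (!is.null(dims)) {
    assert_that(max(dims) <= ncol(coords), "dims exceed available components")
    coords <- coords[, dims, drop = FALSE]
  }
  kn <- knn_indices(coords, k)
  g <- snn_graph(kn$idx)
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(memb)])
  list(labels = setNames(as.integer(labels), rownames(coords)),
       modularity = igraph::modularity(cl), resolution = resolution, k = k)
}

#' Weighted joint neighbors across modalities
#'
#' For each modality m and cell i, d_within is the distance from the cell to
#' the mean of its k nearest neighbors found in m, and d_cross the distance
#' to the mean of its k nearest neighbors found in the other modality; the
#' modality affinity s_m = max(eps, d_cross - d_within) is normalized to
#' per-cell weights summing to 1. The joint distance d(i, j) =
#' w_rna(i) d_rna(i, j) / sigma_rna(i) + w_atac(i) d_atac(i, j) /
#' sigma_atac(i) with sigma the distance to the k-th neighbor; joint kNN is
#' computed on it.
#'
#' @param rna_latent,atac_latent reductions over the identical cell set.
#' @param k neighbors (default 20).
#' @param eps affinity floor.
#' @return list(weights data.frame, joint_idx, joint_coords-free distances).
#' @export
weighted_joint_neighbors <- function(rna_latent, atac_latent, k = 20, eps = 1e-4) {
  a <- if (is.list(rna_latent)) rna_latent$embedding else rna_latent
  b <- if (is.list(atac_latent)) atac_latent$embedding else atac_latent
  assert_that(nrow(a) == nrow(b) && all(rownames(a) == rownames(b)),
              "modalities must cover the identical cell set")
  n <- nrow(a)
  ka <- knn_indices(a, k); kb <- knn_indices(b, k)
  affinity <- function(coords, own, other) {
    d_within <- vapply(seq_len(n), function(i)
      sqrt(sum((coords[i, ] - colMeans(coords[own$idx[i, ], , drop = FALSE]))^2)), 0)
    d_cross <- vapply(seq_len(n), function(i)
      sqrt(sum((coords[i, ] - colMeans(coords[other$idx[i, ], , drop = FALSE]))^2)), 0)
    pmax(eps, d_cross - d_within)
  }
  s_rna <- affinity(a, ka, kb)
  s_atac <- affinity(b, kb, ka)
  w_rna <- s_rna / (s_rna + s_atac)
  w_atac <- 1 - w_rna
  sig_a <- pmax(ka$dist[, k], 1e-12)
  sig_b <- pmax(kb$dist[, k], 1e-12)
  joint <- ka$d / sig_a * w_rna + kb$d / sig_b * w_atac   # row-scaled
  diag(joint) <- Inf
  idx <- t(apply(joint, 1, function(r) order(r)[seq_len(k)]))
  list(weights = data.frame(cell_id = rownames(a), w_rna = w_rna,
                            w_atac = w_atac, stringsAsFactors = FALSE),
       joint_idx = idx, joint_dist = joint)
}

#' MST pseudotime over cluster centroids
#'
#' Cluster centroids are computed in the joint latent space; an MST is built
#' over the complete centroid graph (Euclidean); the root is the centroid of
#' the cluster holding the most root cells; a cell's pseudotime is the tree
#' path length from the root centroid to its cluster centroid plus the signed
#' scalar projection of the cell onto the incoming MST edge (clamped at 0).
#' Branch points are MST nodes of degree >= 3; terminal states are leaves.
#'
#' @param latent cells x dims matrix (joint space).
#' @param clusters per-cell integer labels (0-based).
#' @param root_cells non-empty vector of root cell ids.
#' @return list(pseudotime named per cell, root_cluster, mst_edges,
#'   branch_nodes, terminal_nodes).
#' @export
mst_pseudotime <- function(latent, clusters, root_cells) {
  assert_that(length(root_cells) > 0, "root_cells must be non-empty")
  coords <- if (is.list(latent)) latent$embedding else latent
  cl <- clusters[rownames(coords)]
  labs <- sort(unique(cl))
  cent <- t(vapply(labs, function(l)
    colMeans(coords[cl == l, , drop = FALSE]), numeric(ncol(coords))))
  rownames(cent) <- labs
  root_cluster <- labs[which.max(vapply(labs, function(l)
    sum(rownames(coords)[cl == l] %in% root_cells), 0))]
  if (length(labs) == 1) {
    dirv <- prcomp(coords, rank. = 1)$rotation[, 1]
    proj <- as.vector((coords - rep(cent[1, ], each = nrow(coords))) %*% dirv)
    pt <- proj - min(proj[rownames(coords) %in% root_cells])
    return(list(pseudotime = setNames(pmax(0, pt), rownames(coords)),
                root_cluster = root_cluster, mst_edges = NULL,
                branch_nodes = integer(), terminal_nodes = integer()))
  }
  dmat <- as.matrix(stats::dist(cent))
  g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  ridx <- match(as.character(root_cluster), labs)
  plen <- igraph::distances(mst, v = ridx)[1, ]
  parent <- rep(NA_integer_, length(labs))
  for (v in seq_along(labs)) {
    if (v == ridx) next
    path <- igraph::shortest_paths(mst, from = ridx, to = v)$vpath[[1]]
    parent[v] <- as.integer(path[length(path) - 1])
  }
  deg <- igraph::degree(mst)
  pt <- numeric(nrow(coords))
  for (v in seq_along(labs)) {
    cells_v <- which(cl == labs[v])
    if (length(cells_v) == 0) next
    if (is.na(parent[v])) {
      nb <- as.integer(igraph::neighbors(mst, v))
      edge <- cent[nb[1], ] - cent[v, ]        # root: project on first outgoing edge
    } else {
      edge <- cent[v, ] - cent[parent[v], ]    # incoming edge direction
    }
    u <- edge / sqrt(sum(edge^2))
    proj <- as.vector((coords[cells_v, , drop = FALSE] -
                         rep(cent[v, ], each = length(cells_v))) %*% u)
    pt[cells_v] <- plen[v] + proj
  }
  pt <- pmax(0, pt)
  edges <- igraph::as_edgelist(mst, names = FALSE)
  list(pseudotime = setNames(pt, rownames(coords)),
       root_cluster = root_cluster,
       mst_edges = data.frame(from = labs[edges[, 1]],
                              to = labs[edges[, 2]]),
       branch_nodes = labs[deg >= 3],
       terminal_nodes = setdiff(labs[deg == 1], root_cluster))
}
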