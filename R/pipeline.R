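#' Run the full multiome workflow on synthetic data
#'
#' Chains the stages simulate -> qc -> sex -> cluster -> de -> link -> motif
#' -> grn -> comm, writing each stage's tables (TSV) into `outdir`. The
#' output is a pure function of (config, synth, seed): re-running with the
#' same arguments reproduces every file byte for byte.
#'
#' @param outdir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param synth a [synth_config()].
#' @param seed integer seed (default `config$seed`).
#' @param stages subset of stages to run (default all); each stage requires
#'   its predecessors' in-memory results, so a stage whose inputs are missing
#'   fails with an error naming the stage.
#' @param state result list from a previous [run_pipeline()] call, so stages
#'   can be run incrementally (e.g. by the numbered analysis scripts).
#' @return invisible list with all stage results.
#' @export
run_pipeline <- function(outdir, config = pipeline_config(),
                         synth = synth_config(), seed = config$seed,
                         stages = c("simulate", "qc", "sex", "cluster", "de",
                                    "link", "motif", "grn", "comm"),
                         state = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- if (is.null(state)) list() else state
  t_stage <- Sys.time()
  tick <- function(stage) {
    log_stage(stage, "done in %.1f s", as.numeric(Sys.time() - t_stage, units = "secs"))
    t_stage <<- Sys.time()
  }
  need <- function(stage, what) {
    assert_that(!is.null(what), "stage '%s' is missing a required input", stage)
    what
  }
  out <- function(name) file.path(outdir, name)

  if ("simulate" %in% stages) {
    sim <- simulate_multiome(synth, seed = derive_seed(seed, "simulate"))
    res$sim <- sim
    write_count_matrix(sim$rna, out("rna.mtx"), out("rna_features.tsv"),
                       out("rna_barcodes.tsv"))
    write_count_matrix(sim$atac, out("atac.mtx"), out("atac_features.tsv"),
                       out("atac_barcodes.tsv"))
    write_peaks_bed(sim$peaks[, c("chrom", "start", "end", "gc",
                                  "mean_accessibility")], out("peaks.bed"))
    write_gene_model(sim$genes, out("genes.tsv"))
    write_fragments(sim$fragments, out("fragments.tsv"))
    write_jaspar_pfm(sim$motifs, out("motifs.jaspar"))
    write_tsv(sim$lr_table, out("lr_pairs.tsv"))
    write_tsv(sim$truth$cells, out("ground_truth_cells.tsv"))
    write_tsv(sim$truth$de_genes, out("ground_truth_degs.tsv"))
    write_tsv(sim$truth$links, out("ground_truth_links.tsv"))
    write_tsv(sim$truth$tf_edges, out("ground_truth_tf_edges.tsv"))
    log_stage("simulate", "cells: %d, genes: %d, peaks: %d",
              ncol(sim$rna), nrow(sim$rna), nrow(sim$atac))
    tick("simulate")
  }
  sim <- res$sim

  if ("qc" %in% stages) {
    sim <- need("qc", sim)
    meta <- sim$truth$cells
    rna_qc <- compute_rna_qc(sim$rna, sim$genes)
    ns <- compute_nucleosome_signal(sim$fragments, colnames(sim$rna))
    tss <- compute_tss_enrichment(sim$fragments, sim$genes, colnames(sim$rna))
    metrics <- data.frame(rna_qc,
                          n_count_atac = as.numeric(Matrix::colSums(sim$atac)),
                          nucleosome_signal = unname(ns),
                          tss_enrichment = unname(tss))
    flt <- filter_cells(metrics, config)
    peaks_kept <- filter_peaks(sim$peaks,
                               standard_chroms = c(synth$autosomes, synth$chrY_name),
                               config = config)
    types <- call_cell_types(sim$rna)
    rna_clean <- drop_mito_features(sim$rna, sim$genes)
    keep <- intersect(flt$retained, types$cell_id[types$label != "excluded"])
    res$qc <- list(metrics = metrics, retained = flt$retained,
                   exclusions = flt$exclusions, peaks = peaks_kept,
                   types = types, rna_clean = rna_clean, cells = keep)
    write_tsv(metrics, out("cell_metrics.tsv"))
    write_tsv(types, out("cell_types.tsv"))
    write_peaks_bed(peaks_kept[, c("chrom", "start", "end", "gc",
                                   "mean_accessibility")], out("peaks_retained.bed"))
    tick("qc")
  }

  if ("sex" %in% stages) {
    qc <- need("sex", res$qc)
    need("sex", sim$fragments)
    meta <- sim$truth$cells
    cells <- qc$cells
    norm <- lognormalize(qc$rna_clean[, cells, drop = FALSE])
    chrY_sig <- sim$genes$gene_id[sim$genes$is_chrY]
    score <- rank_module_score(norm, chrY_sig)
    ycount <- chrY_fragment_counts(sim$fragments, qc$peaks, config$chrY_region,
                                   cells, config$chrY_name)
    ref_stage <- utils::tail(synth$stages, 1)
    reference <- list(
      XY = intersect(cells, meta$cell_id[meta$sex == "XY" & meta$stage == ref_stage]),
      XX = intersect(cells, meta$cell_id[meta$sex == "XX" & meta$stage == ref_stage]))
    calls <- assign_sex(score, ycount, reference)
    res$sex <- list(calls = calls, norm = norm, reference = reference)
    write_tsv(calls, out("sex_calls.tsv"))
    tick("sex")
  }

  if ("cluster" %in% stages) {
    sx <- need("cluster", res$sex)
    qc <- res$qc
    meta <- sim$truth$cells
    cells <- sx$calls$cell_id[sx$calls$call != "ambiguous"]
    norm <- sx$norm[, cells, drop = FALSE]
    pca <- pca_reduce(norm, n_comp = max(config$rna_dims))
    lsi <- tfidf_lsi(sim$atac[qc$peaks$peak_id, cells], n_comp = max(config$atac_dims))
    wnn <- weighted_joint_neighbors(
      pca$embedding[, config$rna_dims, drop = FALSE],
      lsi$embedding[, config$atac_dims, drop = FALSE], k = config$cluster_k)
    joint <- cbind(scale(pca$embedding[, config$rna_dims, drop = FALSE]),
                   scale(lsi$embedding[, config$atac_dims, drop = FALSE]))
    cl <- snn_cluster(pca, dims = config$rna_dims, k = config$cluster_k,
                      resolution = config$cluster_resolution,
                      seed = derive_seed(seed, "cluster"))
    roots <- intersect(cells, meta$cell_id[meta$stage == synth$stages[1] &
                                             meta$population == "pgc"])
    pt <- mst_pseudotime(joint, cl$labels, roots)
    res$cluster <- list(cells = cells, pca = pca, lsi = lsi, wnn = wnn,
                        clusters = cl, pseudotime = pt, norm = norm)
    write_tsv(data.frame(cell_id = cells, cluster = cl$labels[cells],
                         pseudotime = pt$pseudotime[cells],
                         w_rna = wnn$weights$w_rna, w_atac = wnn$weights$w_atac),
              out("clusters.tsv"))
    write_tsv(data.frame(cell_id = cells,
                         round(pca$embedding[cells, , drop = FALSE], 6)),
              out("latents_rna.tsv"))
    tick("cluster")
  }

  if ("de" %in% stages) {
    cs <- need("de", res$cluster)
    meta <- sim$truth$cells
    cells <- cs$cells
    atac_norm <- lognormalize(sim$atac[res$qc$peaks$peak_id, cells, drop = FALSE])
    pgc <- function(sex, stage) intersect(cells, meta$cell_id[
      meta$sex == sex & meta$stage == stage & meta$population == "pgc" & !meta$doublet])
    degs <- list(); daps <- list()
    for (st in synth$stages) {
      g1 <- pgc("XX", st); g2 <- pgc("XY", st)
      degs[[st]] <- find_markers(cs$norm, g1, g2, min_pct = config$de_min_pct,
                                 logfc_threshold = config$de_logfc,
                                 alpha = config$alpha)
      daps[[st]] <- find_markers(atac_norm, g1, g2, min_pct = config$dap_min_pct,
                                 logfc_threshold = config$dap_logfc,
                                 alpha = config$alpha)
      log_stage("de", "%s: %d DEGs, %d DAPs significant", st,
                sum(degs[[st]]$significant), sum(daps[[st]]$significant))
    }
    pgc_all <- intersect(cells, meta$cell_id[meta$population == "pgc" & !meta$doublet])
    soma_all <- intersect(cells, meta$cell_id[meta$population != "pgc" & !meta$doublet])
    germ_de <- find_markers(cs$norm, pgc_all, soma_all,
                            min_pct = config$de_min_pct,
                            logfc_threshold = config$de_logfc,
                            alpha = config$alpha)
    anno <- annotate_peaks(res$qc$peaks, sim$genes, config$tss_region)
    res$de <- list(degs = degs, daps = daps, germ_de = germ_de,
                   atac_norm = atac_norm, annotation = anno)
    for (st in synth$stages) {
      write_tsv(degs[[st]], out(sprintf("degs_%s.tsv", st)))
      write_tsv(daps[[st]], out(sprintf("daps_%s.tsv", st)))
    }
    write_tsv(germ_de, out("degs_germ_vs_soma.tsv"))
    write_tsv(anno, out("peak_annotation.tsv"))
    tick("de")
  }

  if ("link" %in% stages) {
    de <- need("link", res$de)
    cs <- res$cluster
    deg_ids <- unique(unlist(lapply(de$degs, function(d)
      d$feature[d$significant])))
    cand <- candidate_pairs(res$qc$peaks, sim$genes, config$link_distance)
    cand <- cand[cand$gene_id %in% deg_ids, , drop = FALSE]
    feats <- res$qc$peaks[, c("peak_id", "gc", "mean_accessibility")]
    links <- link_peaks(de$atac_norm, cs$norm, cand, feats,
                        n_background = config$n_background,
                        seed = derive_seed(seed, "link"),
                        link_p = config$link_p)
    res$link <- list(links = links, deg_ids = deg_ids)
    write_tsv(links, out("links.tsv"))
    tick("link")
  }

  if ("motif" %in% stages) {
    lk <- need("motif", res$link)
    seqs <- setNames(res$qc$peaks$sequence, res$qc$peaks$peak_id)
    pwms <- lapply(sim$motifs, pfm_to_pwm)
    scan <- scan_sequences(seqs, pwms, config$motif_threshold_frac)
    dap_ids <- unique(unlist(lapply(res$de$daps, function(d)
      d$feature[d$significant])))
    fg <- unique(lk$links$peak_id[lk$links$retained &
                                    lk$links$peak_id %in% dap_ids])
    feats <- res$qc$peaks[, c("peak_id", "gc", "mean_accessibility")]
    bg <- matched_background_peaks(fg, feats,
                                   n = min(config$n_background * 2,
                                           nrow(feats) - length(fg)),
                                   seed = derive_seed(seed, "motifbg"))
    enr <- motif_enrichment(fg, bg, scan$matrix)
    dev <- chromvar_deviations(sim$atac[res$qc$peaks$peak_id, res$cluster$cells],
                               scan$matrix, feats,
                               n_iterations = config$deviation_iterations,
                               seed = derive_seed(seed, "chromvar"))
    res$motif <- list(scan = scan, enrichment = enr, deviations = dev,
                      foreground = fg, background = bg)
    write_tsv(scan$hits, out("motif_hits.tsv"))
    write_tsv(enr, out("motif_enrichment.tsv"))
    write_tsv(data.frame(motif_id = rownames(dev$z),
                         round(dev$z, 6), check.names = FALSE),
              out("motif_deviation_z.tsv"))
    tick("motif")
  }

  if ("grn" %in% stages) {
    mo <- need("grn", res$motif)
    meta <- sim$truth$cells
    st <- utils::tail(synth$stages, 1)
    sex_de <- res$de$degs[[st]]
    cand_rows <- list()
    for (sx in synth$sexes) {
      focal <- intersect(res$cluster$cells, meta$cell_id[
        meta$sex == sx & meta$stage == st & meta$population == "pgc"])
      tri <- triage_tfs(sex_de, res$de$germ_de, mo$enrichment, mo$deviations,
                        sim$tf2motif, focal, alpha = config$alpha,
                        de_logfc = config$de_logfc)
      tri$focal_sex <- sx
      # a TF is evaluated against the PGC population of the sex it favors
      up_sex <- ifelse(tri$sex_log2fc >= 0, "XX", "XY")
      cand_rows[[sx]] <- tri[!is.na(up_sex) & up_sex == sx, , drop = FALSE]
    }
    candidates <- do.call(rbind, cand_rows)
    rownames(candidates) <- NULL
    deg_e13 <- sex_de$feature[sex_de$significant]
    net <- assign_targets(candidates, res$link$links, mo$scan$hits, deg_e13)
    xreg <- cross_regulation(candidates, res$link$links, mo$scan$hits,
                             sim$genes, res$qc$peaks, config$tss_region)
    summ <- network_summary(net, deg_e13, res$link$links)
    res$grn <- list(candidates = candidates, network = net,
                    cross_regulation = xreg, summary = summ)
    write_tsv(candidates, out("tf_candidates.tsv"))
    write_tsv(net$edges, out("network_edges.tsv"))
    write_tsv(as.data.frame(xreg), out("cross_regulation.tsv"))
    write_tsv(summ$per_tf, out("network_summary.tsv"))
    tick("grn")
  }

  if ("comm" %in% stages) {
    need("comm", res$cluster)
    meta <- sim$truth$cells
    cells <- res$cluster$cells
    norm_all <- lognormalize(res$qc$rna_clean[, cells, drop = FALSE])
    results <- list()
    for (sx in synth$sexes) for (st in synth$stages) {
      sender <- intersect(cells, meta$cell_id[
        meta$sex == sx & meta$stage == st & meta$population == "supporting" & !meta$doublet])
      receiver <- intersect(cells, meta$cell_id[
        meta$sex == sx & meta$stage == st & meta$population == "pgc" & !meta$doublet])
      nm <- paste0(sx, ".", st)
      results[[nm]] <- test_lr_table(norm_all, sender, receiver, sim$lr_table,
                                     n_perm = config$permutations,
                                     seed = derive_seed(seed, nm),
                                     min_frac = config$lr_min_frac,
                                     alpha = config$alpha)
    }
    cnt <- count_interactions(results, config$alpha)
    res$comm <- list(results = results, counts = cnt)
    all_res <- do.call(rbind, lapply(names(results), function(nm)
      cbind(condition = nm, results[[nm]])))
    write_tsv(all_res, out("interactions.tsv"))
    write_tsv(cnt$counts, out("interaction_counts.tsv"))
    tick("comm")
  }

  invisible(res)
}
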