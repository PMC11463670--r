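#' Synthetic multiome configuration
#'
#' Defines the study conditions the generator emulates: XX and XY fetal gonads
#' at three embryonic stages (E11.5, E12.5, E13.5), each containing PGCs,
#' supporting cells and other somatic cells; Y-linked genes and chrY peaks
#' present only in XY cells; mitochondrial genes at a fixed count fraction;
#' sex-differential genes planted per stage; peaks coupled to gene expression
#' through a shared per-cell activity; TF consensus motifs planted in the
#' linked peaks of their targets; ligand-receptor pairs co-expressed between
#' supporting cells and PGCs; and cross-population doublets.
#'
#' @param ... overrides for any field (see source for the full list).
#' @return A named list of class `synth_config`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    sexes = c("XX", "XY"),
    stages = c("E11.5", "E12.5", "E13.5"),
    # cells per sex x stage: ~3,000 nuclei total, PGC-enriched like the
    # dissected gonad libraries
    n_pgc = 250, n_supporting = 150, n_somatic = 100,
    n_genes = 2000, n_peaks = 5000,
    lib_meanlog = log(6000), lib_sdlog = 0.25,       # RNA library sizes
    atac_meanlog = log(5000), atac_sdlog = 0.3,      # ATAC library sizes
    nb_size = 10,                                    # NB dispersion (size)
    n_chrY_genes = 4, n_mito_genes = 13, mito_frac = 0.05,
    chrY_gene_mean = 30,
    doublet_rate = 0.05,
    # planted sex-DE genes per stage (split evenly between directions) and
    # their log2 effect on the PGC mean
    n_de_genes = c(E11.5 = 16, E12.5 = 80, E13.5 = 100),
    de_effect = 1,
    de_base_mean = 4,
    # peak-gene coupling
    link_strength = 0.5,
    n_extra_links = 100,
    link_min_offset = 10e3, link_max_offset = 200e3,
    de_min_separation = 7e5,
    # TF regulatory structure (acting at E13.5)
    n_tfs_xx = 3, n_tfs_xy = 2, targets_per_tf = 8,
    motif_length = 10, n_decoy_motifs = 5,
    # ligand-receptor structure
    n_lr_xx = 6, n_lr_xy = 4, n_lr_shared = 3, n_lr_null = 7,
    lr_mean = 6,
    # fragments
    frag_per_count = 1 / 25, tss_frag_frac = 0.5,
    frag_sub_mean = 80, frag_sub_sd = 15,
    frag_mono_mean = 200, frag_mono_sd = 25, frag_mono_frac = 0.4,
    chrY_frag_mean = 8, n_chrY_peaks = 21,
    # genome layout
    autosomes = paste0("chr", 1:5), chrom_length = 25e6,
    chrY_name = "chrY", chrY_length = 9e7, mito_name = "chrM",
    peak_width_range = c(300, 500),
    pop_signature_frac = 0.08, pop_signature_fold = 2,
    stage_signature_frac = 0.05, stage_signature_fold = 1.4
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0, "unknown synth_config field(s): %s",
              paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  assert_that(cfg$doublet_rate >= 0 && cfg$doublet_rate < 1,
              "doublet_rate must lie in [0, 1)")
  assert_that(all(unlist(cfg[c("n_pgc", "n_supporting", "n_somatic",
                               "n_genes", "n_peaks")]) > 0),
              "cell/gene/peak counts must be positive")
  class(cfg) <- c("synth_config", "list")
  cfg
}

# Marker-gene table: analogues of the published population markers, expressed
# only in the listed population (exact zeros elsewhere so the count-based
# triage rules are exercised as printed).
marker_table <- function() {
  data.frame(
    gene = c("Ddx4", "Pou5f1",
             "Wt1", "Foxl2", "Runx1", "Sox9", "Tspan8",
             "Insl3", "Pdgfra", "Nr2f2", "Mafb", "Plvap", "Pecam1", "Krt19"),
    population = c("pgc", "pgc",
                   rep("supporting", 5),
                   rep("somatic", 7)),
    mean = c(8, 6, 8, 6, 6, 6, 4, 4, 6, 6, 3, 3, 3, 2),
    sex = c(NA, NA, NA, "XX", "XX", "XY", NA, "XY", NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

BASES <- c("A", "C", "G", "T")

random_consensus <- function(len) paste(sample(BASES, len, replace = TRUE), collapse = "")

consensus_pfm <- function(consensus, hit = 12, miss = 1) {
  b <- strsplit(consensus, "")[[1]]
  m <- matrix(miss, 4, length(b), dimnames = list(BASES, NULL))
  m[cbind(match(b, BASES), seq_along(b))] <- hit
  m
}

#' Simulate a paired RNA/ATAC multiome with planted ground truth
#'
#' RNA counts are gamma-Poisson (negative binomial) around population- and
#' stage-specific means scaled by per-cell library size; ATAC peak counts are
#' Poisson, with planted linked peaks coupled to the normalized expression of
#' their gene so the count-scale Pearson correlation equals the configured
#' strength in expectation; chrY genes and peaks are zero in XX cells by
#' construction; fragments carry a bimodal length mixture with TSS-centered
#' pileup and chrY fragments only for XY barcodes; doublets are sums of two
#' cross-population donors.
#'
#' @param config a [synth_config()].
#' @param seed integer seed; the output is a pure function of (config, seed).
#' @return List with elements `rna`, `atac` (CountMatrix), `peaks` (data.frame
#'   with gc, mean_accessibility and synthetic sequence), `genes` (gene model),
#'   `fragments` (data.frame), `motifs` (JASPAR-style PFM list), `tf2motif`
#'   (named map), `lr_table` (pair table), and `truth` (planted ground truth).
#' @export
simulate_multiome <- function(config = synth_config(), seed = 1L) {
  set.seed(as.integer(seed))
  cfg <- config
  sexes <- cfg$sexes; stages <- cfg$stages
  pops <- c(pgc = cfg$n_pgc, supporting = cfg$n_supporting, somatic = cfg$n_somatic)

  ## ---- cells -------------------------------------------------------------
  grid <- expand.grid(population = names(pops), stage = stages, sex = sexes,
                      stringsAsFactors = FALSE)
  grid$n <- pops[grid$population]
  cells <- grid[rep(seq_len(nrow(grid)), grid$n), c("sex", "stage", "population")]
  rownames(cells) <- NULL
  n_cells <- nrow(cells)
  cells$cell_id <- sprintf("cell_%04d", seq_len(n_cells))
  cells$group <- paste(cells$sex, cells$stage, cells$population, sep = ".")
  groups <- unique(cells$group)

  ## ---- gene universe -----------------------------------------------------
  mk <- marker_table()
  chrY_genes <- c("Kdm5d", "Eif2s3y", "Uty", "Ddx3y")[seq_len(min(4, cfg$n_chrY_genes))]
  if (cfg$n_chrY_genes > 4)
    chrY_genes <- c(chrY_genes, sprintf("chrYg%02d", seq_len(cfg$n_chrY_genes - 4)))
  mito_genes <- sprintf("mt-%02d", seq_len(cfg$n_mito_genes))
  lr_specs <- build_lr_specs(cfg)
  lr_genes <- unique(unlist(c(lr_specs$ligand_subunits, lr_specs$receptor_subunits)))
  tf_genes <- c(sprintf("TfXX%d", seq_len(cfg$n_tfs_xx)),
                sprintf("TfXY%d", seq_len(cfg$n_tfs_xy)))
  n_special <- length(mk$gene) + length(chrY_genes) + length(mito_genes) +
    length(lr_genes) + length(tf_genes)
  assert_that(cfg$n_genes > n_special + sum(cfg$n_de_genes) + 50,
              "n_genes too small for the planted structure")
  n_regular <- cfg$n_genes - n_special
  regular <- sprintf("g%04d", seq_len(n_regular))
  gene_ids <- c(mk$gene, chrY_genes, mito_genes, lr_genes, tf_genes, regular)

  ## ---- gene model (placed first so DE genes can be spaced) ----------------
  genes <- place_genes(cfg, gene_ids, chrY_genes, mito_genes)

  ## ---- planted DE genes (drawn from regular genes, per stage) -------------
  # same-direction DE genes are kept >= de_min_separation apart so a planted
  # linked peak cannot sit within linkage distance of a second co-directional
  # DE gene (keeps the planted network identifiable)
  tf_sex <- c(rep("XX", cfg$n_tfs_xx), rep("XY", cfg$n_tfs_xy))
  names(tf_sex) <- tf_genes
  de_genes <- pick_de_genes(cfg, genes, regular, sexes, stages, tf_sex)

  ## ---- expression model: mean count per gene x group ----------------------
  base <- rlnorm(cfg$n_genes, 0, 1)
  names(base) <- gene_ids
  base[de_genes$gene_id] <- cfg$de_base_mean
  E <- matrix(base, cfg$n_genes, length(groups),
              dimnames = list(gene_ids, groups))
  gmeta <- unique(cells[, c("group", "sex", "stage", "population")])
  gmeta <- gmeta[match(groups, gmeta$group), ]
  gsex <- gmeta$sex; gstage <- gmeta$stage; gpop <- gmeta$population

  # markers: zero outside their population (and sex where sex-specific)
  for (i in seq_len(nrow(mk))) {
    on <- gpop == mk$population[i] &
      (is.na(mk$sex[i]) | gsex == mk$sex[i])
    E[mk$gene[i], ] <- ifelse(on, mk$mean[i], 0)
  }
  # chrY genes: all XY cells, zero in XX
  E[chrY_genes, ] <- rep(ifelse(gsex == "XY", cfg$chrY_gene_mean, 0),
                         each = length(chrY_genes))
  # sex-DE genes: effect applied to the PGC mean of the up sex at that stage
  for (i in seq_len(nrow(de_genes))) {
    on <- gsex == de_genes$up_sex[i] & gstage == de_genes$stage[i] & gpop == "pgc"
    E[de_genes$gene_id[i], on] <- E[de_genes$gene_id[i], on] * 2^de_genes$effect[i]
  }
  # TFs: germline-enriched, sex-biased at E13.5
  for (tf in tf_genes) {
    E[tf, ] <- ifelse(gpop == "pgc", cfg$de_base_mean, 0.4)
    on <- gpop == "pgc" & gsex == tf_sex[tf] & gstage == "E13.5"
    E[tf, on] <- E[tf, on] * 2^cfg$de_effect
  }
  # LR genes
  for (i in seq_len(nrow(lr_specs))) {
    sp <- lr_specs$specificity[i]
    for (g in lr_specs$ligand_subunits[[i]]) {
      E[g, ] <- if (sp == "null") 1 else
        ifelse(gpop == "supporting" & (sp == "shared" | gsex == sp), cfg$lr_mean, 0)
    }
    for (g in lr_specs$receptor_subunits[[i]]) {
      E[g, ] <- if (sp == "null") 1 else
        ifelse(gpop == "pgc" & (sp == "shared" | gsex == sp), cfg$lr_mean, 0)
    }
  }
  # population and stage signatures over regular, non-planted genes
  free <- setdiff(regular, de_genes$gene_id)
  for (p in unique(gpop)) {
    sig <- sample(free, round(cfg$pop_signature_frac * length(free)))
    E[sig, gpop == p] <- E[sig, gpop == p] * cfg$pop_signature_fold
  }
  for (si in seq_along(stages)) {
    sig <- sample(free, round(cfg$stage_signature_frac * length(free)))
    E[sig, gstage == stages[si]] <- E[sig, gstage == stages[si]] *
      cfg$stage_signature_fold^(si - 1)
  }
  # mitochondrial genes: fixed fraction of the per-group count mass
  nonmito <- setdiff(gene_ids, mito_genes)
  mito_mass <- cfg$mito_frac / (1 - cfg$mito_frac) *
    colSums(E[nonmito, , drop = FALSE]) / length(mito_genes)
  E[mito_genes, ] <- rep(mito_mass, each = length(mito_genes))

  ## ---- RNA counts ---------------------------------------------------------
  lib <- rlnorm(n_cells, cfg$lib_meanlog, cfg$lib_sdlog)
  P <- sweep(E, 2, colSums(E), "/")              # relative profile per group
  rna <- matrix(0L, cfg$n_genes, n_cells, dimnames = list(gene_ids, cells$cell_id))
  for (gr in groups) {
    idx <- which(cells$group == gr)
    mu <- outer(P[, gr], lib[idx])
    rna[, idx] <- rnbinom(length(mu), mu = mu, size = cfg$nb_size)
  }

  ## ---- peaks, links, motifs ----------------------------------------------
  layout <- place_peaks(cfg, genes, de_genes, tf_genes, tf_sex)
  peaks <- layout$peaks
  links <- layout$links
  n_peaks <- nrow(peaks)

  # normalized expression used as the shared latent for peak coupling
  totals <- colSums(rna)
  norm_gene <- function(g) log1p(rna[g, ] / pmax(totals, 1) * 1e4)

  atac_lib <- rlnorm(n_cells, cfg$atac_meanlog, cfg$atac_sdlog)
  w <- rgamma(n_peaks, shape = 2, scale = 0.5)
  w[peaks$chrom == cfg$chrY_name] <- 0.5
  lam_base <- outer(w / sum(w), atac_lib)        # peaks x cells
  lam_base[peaks$chrom == cfg$chrY_name, cells$sex == "XX"] <- 0
  atac <- matrix(rpois(length(lam_base), lam_base), n_peaks, n_cells,
                 dimnames = list(peaks$peak_id, cells$cell_id))

  # overwrite linked peaks with coupled Poisson counts; beta is solved so the
  # expected count-scale Pearson r equals the configured strength
  links$beta <- NA_real_
  for (i in seq_len(nrow(links))) {
    g <- norm_gene(links$gene_id[i])
    pid <- links$peak_id[i]
    lam0 <- w[match(pid, peaks$peak_id)] / sum(w) * exp(cfg$atac_meanlog)
    beta <- solve_link_beta(links$strength[i], mean(g), var(g), lam0)
    lam <- lam0 + beta * g
    atac[pid, ] <- rpois(n_cells, lam)
    links$beta[i] <- beta
  }
  peaks$mean_accessibility <- rowMeans(atac)

  ## ---- motif PFMs and planted hit records ---------------------------------
  consensi <- vapply(seq_len(length(tf_genes) + cfg$n_decoy_motifs),
                     function(i) random_consensus(cfg$motif_length), "")
  motif_ids <- c(sprintf("MA%04d.%s", seq_along(tf_genes), tf_genes),
                 sprintf("MA9%03d.decoy%d", seq_len(cfg$n_decoy_motifs),
                         seq_len(cfg$n_decoy_motifs)))
  motifs <- lapply(consensi, consensus_pfm)
  names(motifs) <- motif_ids
  tf2motif <- setNames(motif_ids[seq_along(tf_genes)], tf_genes)

  seq_out <- build_peak_sequences(cfg, peaks, layout$planned_hits,
                                  consensi[seq_along(tf_genes)], tf2motif)
  peaks$sequence <- seq_out$sequences
  peaks$gc <- seq_out$gc
  motif_hits <- seq_out$hits

  ## ---- fragments ----------------------------------------------------------
  fragments <- build_fragments(cfg, cells, genes, peaks, atac_lib)

  ## ---- doublets -----------------------------------------------------------
  rna_cm <- count_matrix(rna, gene_ids, cells$cell_id, "rna")
  atac_cm <- count_matrix(atac, peaks$peak_id, cells$cell_id, "atac")
  dbl <- inject_doublets(rna_cm, atac_cm, cells$population, cfg$doublet_rate,
                         seed = derive_seed(seed, "doublets"))
  cells$doublet <- dbl$is_doublet

  # all genes sex-differential in PGCs by construction, per stage: the planted
  # DE set plus chrY genes, the E13.5-acting TFs, and sex-specific receptor
  # subunits (expressed only in PGCs of one sex)
  sexed_rec <- unlist(lr_specs$receptor_subunits[lr_specs$specificity %in% sexes])
  sex_de_truth <- do.call(rbind, lapply(stages, function(st) {
    g <- c(de_genes$gene_id[de_genes$stage == st], chrY_genes, sexed_rec,
           if (st == "E13.5") tf_genes)
    data.frame(gene_id = g, stage = st, stringsAsFactors = FALSE)
  }))

  truth <- list(
    cells = cells[, c("cell_id", "sex", "stage", "population", "doublet")],
    de_genes = de_genes,
    sex_de_truth = sex_de_truth,
    links = links,
    tf_edges = layout$tf_edges,
    tf_sex = tf_sex,
    motif_hits = motif_hits,
    lr_pairs = lr_specs[, c("pair_id", "specificity", "pathway")],
    doublet_donors = dbl$donors
  )

  list(rna = dbl$rna, atac = dbl$atac,
       peaks = peaks, genes = genes, fragments = fragments,
       motifs = motifs, tf2motif = tf2motif,
       lr_table = lr_table_from_specs(lr_specs),
       truth = truth, config = cfg)
}

# beta solving r^2 (lam0 + beta m + beta^2 v) = beta^2 v for Poisson(lam0 +
# beta g) against g with mean m, variance v; beta = 0 when r = 0 or v = 0.
solve_link_beta <- function(r, m, v, lam0) {
  if (r <= 0 || v <= 0) return(0)
  assert_that(r < 1, "link strength must be < 1")
  a <- v * (1 - r^2)
  (r^2 * m + sqrt(r^4 * m^2 + 4 * a * r^2 * lam0)) / (2 * a)
}

# Sample planted DE genes so that genes sharing an up-regulated sex (and the
# same-sex TF genes) sit at least de_min_separation apart on the genome.
pick_de_genes <- function(cfg, genes, regular, sexes, stages, tf_sex) {
  pos <- setNames(match(genes$chrom, unique(genes$chrom)) * 10 * cfg$chrom_length +
                    genes$tss, genes$gene_id)
  picked <- list()
  for (s in sexes) picked[[s]] <- unname(pos[names(tf_sex)[tf_sex == s]])
  pool <- sample(regular)
  out <- list(); pi <- 1L
  for (st in stages) {
    nst <- cfg$n_de_genes[[st]]
    dirs <- rep(sexes, length.out = nst)
    chosen <- character(nst)
    for (i in seq_len(nst)) {
      s <- dirs[i]
      repeat {
        assert_that(pi <= length(pool),
                    "cannot place %d separated DE genes; lower n_de_genes or de_min_separation", nst)
        g <- pool[pi]; pi <- pi + 1L
        if (length(picked[[s]]) == 0 ||
            min(abs(pos[g] - picked[[s]])) >= cfg$de_min_separation) {
          picked[[s]] <- c(picked[[s]], unname(pos[g]))
          chosen[i] <- g
          break
        }
      }
    }
    out[[st]] <- data.frame(gene_id = chosen, stage = st, up_sex = dirs,
                            effect = cfg$de_effect, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

place_genes <- function(cfg, gene_ids, chrY_genes, mito_genes) {
  n <- length(gene_ids)
  auto <- setdiff(gene_ids, c(chrY_genes, mito_genes))
  per_chrom <- ceiling(length(auto) / length(cfg$autosomes))
  chrom <- rep(cfg$autosomes, each = per_chrom)[seq_along(auto)]
  idx <- unlist(lapply(table(chrom)[unique(chrom)], seq_len), use.names = FALSE)
  spacing <- floor((cfg$chrom_length - 1e5) / per_chrom)
  start <- 5e4 + (idx - 1) * spacing
  len <- sample(2e3:2e4, length(auto), replace = TRUE)
  strand <- sample(c("+", "-"), length(auto), replace = TRUE)
  df <- data.frame(gene_id = auto, chrom = chrom, start = start,
                   end = start + len, strand = strand, stringsAsFactors = FALSE)
  ystart <- round(seq(2e6, cfg$chrY_length - 2e6, length.out = length(chrY_genes)))
  df <- rbind(df, data.frame(gene_id = chrY_genes, chrom = cfg$chrY_name,
                             start = ystart, end = ystart + 5e3, strand = "+"))
  mstart <- 100 + (seq_along(mito_genes) - 1) * 1000
  df <- rbind(df, data.frame(gene_id = mito_genes, chrom = cfg$mito_name,
                             start = mstart, end = mstart + 800, strand = "+"))
  df <- df[match(gene_ids, df$gene_id), ]
  rownames(df) <- NULL
  df$is_mitochondrial <- df$gene_id %in% mito_genes
  validate_gene_model(df, cfg$chrY_name)
}

# Peak layout: chrY peaks, one linked peak per DE gene and per TF target,
# promoter peaks for TF genes (cross-regulation), extra random links, and
# random background peaks.
place_peaks <- function(cfg, genes, de_genes, tf_genes, tf_sex) {
  width <- function(n) sample(cfg$peak_width_range[1]:cfg$peak_width_range[2],
                              n, replace = TRUE)
  gene_row <- function(g) genes[match(g, genes$gene_id), ]
  linked_peak <- function(g) {
    gi <- gene_row(g)
    off <- sample(cfg$link_min_offset:cfg$link_max_offset, 1) *
      sample(c(-1, 1), 1)
    w <- width(1)
    st <- pmax(0, pmin(gi$tss + off, cfg$chrom_length - w - 1))
    data.frame(chrom = gi$chrom, start = st, end = st + w,
               stringsAsFactors = FALSE)
  }

  peak_rows <- list(); link_rows <- list(); hit_rows <- list(); edge_rows <- list()

  # one linked peak per planted DE gene
  for (i in seq_len(nrow(de_genes))) {
    g <- de_genes$gene_id[i]
    pr <- linked_peak(g)
    peak_rows[[length(peak_rows) + 1L]] <- cbind(pr, role = "de_link")
    link_rows[[length(link_rows) + 1L]] <-
      data.frame(row = length(peak_rows), gene_id = g,
                 strength = cfg$link_strength)
  }
  # TF target edges: targets drawn from same-sex E13.5 DE genes; the TF motif
  # is planted in the target's linked peak
  e13 <- de_genes[de_genes$stage == "E13.5", ]
  used <- character()
  for (tf in tf_genes) {
    pool <- setdiff(e13$gene_id[e13$up_sex == tf_sex[tf]], used)
    assert_that(length(pool) >= cfg$targets_per_tf,
                "not enough E13.5 DE genes to assign targets for %s", tf)
    targets <- sample(pool, cfg$targets_per_tf)
    used <- c(used, targets)
    rows <- vapply(targets, function(g) {
      link_rows[[which(vapply(link_rows, function(l) l$gene_id, "") == g)[1]]]$row
    }, 0)
    edge_rows[[tf]] <- data.frame(tf = tf, target = targets, row = rows,
                                  stringsAsFactors = FALSE)
    for (r in rows)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(tf = tf, row = r)
  }
  # TF promoter peaks + planted cross-regulation (each TF's motif in the next
  # same-sex TF's promoter peak)
  promoter_row <- integer(length(tf_genes)); names(promoter_row) <- tf_genes
  for (tf in tf_genes) {
    gi <- gene_row(tf)
    w <- width(1)
    st <- max(0, gi$tss - floor(w / 2))
    peak_rows[[length(peak_rows) + 1L]] <-
      cbind(data.frame(chrom = gi$chrom, start = st, end = st + w), role = "promoter")
    promoter_row[tf] <- length(peak_rows)
  }
  cross <- list()
  for (s in unique(tf_sex)) {
    grp <- names(tf_sex)[tf_sex == s]
    if (length(grp) < 2) next
    for (i in seq_along(grp)) {
      a <- grp[i]; b <- grp[i %% length(grp) + 1]
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(tf = a, row = promoter_row[b])
      cross[[length(cross) + 1L]] <- data.frame(tf = a, target_tf = b)
    }
  }
  # extra random links over expressed regular genes
  pool <- setdiff(genes$gene_id[!genes$is_mitochondrial & !genes$is_chrY],
                  c(de_genes$gene_id, tf_genes))
  extra <- sample(pool, cfg$n_extra_links)
  for (g in extra) {
    pr <- linked_peak(g)
    peak_rows[[length(peak_rows) + 1L]] <- cbind(pr, role = "extra_link")
    link_rows[[length(link_rows) + 1L]] <-
      data.frame(row = length(peak_rows), gene_id = g,
                 strength = cfg$link_strength)
  }
  # chrY peaks inside the configured region
  ystart <- round(seq(1e6, min(cfg$chrY_length, 9e7) - 1e6,
                      length.out = cfg$n_chrY_peaks))
  for (s in ystart)
    peak_rows[[length(peak_rows) + 1L]] <-
      cbind(data.frame(chrom = cfg$chrY_name, start = s, end = s + width(1)),
            role = "chrY")
  # random background peaks
  n_bg <- cfg$n_peaks - length(peak_rows)
  assert_that(n_bg > 0, "more planted peaks than n_peaks allows")
  bg_chrom <- sample(cfg$autosomes, n_bg, replace = TRUE)
  bg_start <- sample.int(cfg$chrom_length - 1000, n_bg)
  for (i in seq_len(n_bg))
    peak_rows[[length(peak_rows) + 1L]] <-
      cbind(data.frame(chrom = bg_chrom[i], start = bg_start[i],
                       end = bg_start[i] + width(1)), role = "background")

  peaks <- do.call(rbind, peak_rows)
  rownames(peaks) <- NULL
  peaks$peak_id <- paste0(peaks$chrom, ":", peaks$start, "-", peaks$end)
  while (anyDuplicated(peaks$peak_id)) {   # nudge rare coordinate collisions
    d <- which(duplicated(peaks$peak_id))
    peaks$start[d] <- peaks$start[d] + 7L
    peaks$end[d] <- peaks$end[d] + 7L
    peaks$peak_id <- paste0(peaks$chrom, ":", peaks$start, "-", peaks$end)
  }

  links <- do.call(rbind, link_rows)
  links <- data.frame(peak_id = peaks$peak_id[links$row],
                      gene_id = links$gene_id, strength = links$strength,
                      stringsAsFactors = FALSE)
  tf_edges <- do.call(rbind, edge_rows)
  tf_edges <- data.frame(tf = tf_edges$tf, target = tf_edges$target,
                         peak_id = peaks$peak_id[tf_edges$row],
                         stringsAsFactors = FALSE)
  rownames(tf_edges) <- NULL
  planned_hits <- do.call(rbind, hit_rows)
  planned_hits$peak_id <- peaks$peak_id[planned_hits$row]
  list(peaks = peaks, links = links, tf_edges = tf_edges,
       planned_hits = planned_hits,
       cross_edges = if (length(cross)) do.call(rbind, cross) else NULL)
}

# Synthetic peak sequences: random bases at a per-peak GC level, with each
# planted TF consensus substituted at a recorded offset so scanning and
# planting agree exactly.
build_peak_sequences <- function(cfg, peaks, planned_hits, consensi, tf2motif) {
  n <- nrow(peaks)
  gc_target <- stats::rbeta(n, 10, 10)
  widths <- peaks$end - peaks$start
  seqs <- vapply(seq_len(n), function(i) {
    p <- c((1 - gc_target[i]) / 2, gc_target[i] / 2,
           gc_target[i] / 2, (1 - gc_target[i]) / 2)
    paste(sample(BASES, widths[i], replace = TRUE, prob = p), collapse = "")
  }, "")
  names(consensi) <- names(tf2motif)
  hits <- NULL
  if (!is.null(planned_hits) && nrow(planned_hits) > 0) {
    planned_hits$offset <- NA_integer_
    for (i in seq_len(nrow(planned_hits))) {
      pid <- planned_hits$peak_id[i]
      j <- match(pid, peaks$peak_id)
      cons <- consensi[[planned_hits$tf[i]]]
      L <- nchar(cons)
      off <- sample.int(widths[j] - L + 1L, 1L)
      substr(seqs[j], off, off + L - 1L) <- cons
      planned_hits$offset[i] <- off
    }
    hits <- data.frame(tf = planned_hits$tf,
                       motif_id = tf2motif[planned_hits$tf],
                       peak_id = planned_hits$peak_id,
                       offset = planned_hits$offset, strand = "+",
                       stringsAsFactors = FALSE)
    rownames(hits) <- NULL
  }
  gc <- vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("C", "G"))
  }, 0, USE.NAMES = FALSE)
  list(sequences = seqs, gc = gc, hits = hits)
}

# Fragment file contents: bimodal length mixture (sub- vs mono-nucleosomal),
# TSS-centered pileup for half the fragments, chrY peak fragments for XY only.
build_fragments <- function(cfg, cells, genes, peaks, atac_lib) {
  n_cells <- nrow(cells)
  nfrag <- pmax(50L, as.integer(round(atac_lib * cfg$frag_per_count)))
  total <- sum(nfrag)
  barcode <- rep(cells$cell_id, nfrag)
  is_mono <- runif(total) < cfg$frag_mono_frac
  len <- ifelse(is_mono,
                pmax(148, round(rnorm(total, cfg$frag_mono_mean, cfg$frag_mono_sd))),
                pmax(25, pmin(146, round(rnorm(total, cfg$frag_sub_mean, cfg$frag_sub_sd)))))
  auto_genes <- genes[!genes$is_mitochondrial & !genes$is_chrY, ]
  at_tss <- runif(total) < cfg$tss_frag_frac
  gi <- sample.int(nrow(auto_genes), total, replace = TRUE)
  tss_start <- auto_genes$tss[gi] - floor(len / 2) + round(rnorm(total, 0, 80))
  unif_chrom <- sample(cfg$autosomes, total, replace = TRUE)
  unif_start <- sample.int(cfg$chrom_length - 1000L, total, replace = TRUE)
  chrom <- ifelse(at_tss, auto_genes$chrom[gi], unif_chrom)
  start <- pmax(0, ifelse(at_tss, tss_start, unif_start))
  frags <- data.frame(chrom = chrom, start = start, end = start + len,
                      barcode = barcode,
                      count = 1L + rbinom(total, 1L, 0.2),
                      stringsAsFactors = FALSE)
  # chrY fragments: XY barcodes only, placed inside chrY peaks
  ypeaks <- peaks[peaks$chrom == cfg$chrY_name, ]
  xy <- cells$cell_id[cells$sex == "XY"]
  if (nrow(ypeaks) > 0 && length(xy) > 0) {
    ny <- rpois(length(xy), cfg$chrY_frag_mean)
    tot <- sum(ny)
    if (tot > 0) {
      pk <- sample.int(nrow(ypeaks), tot, replace = TRUE)
      w <- ypeaks$end[pk] - ypeaks$start[pk]
      st <- ypeaks$start[pk] + floor(runif(tot) * pmax(1, w - 100))
      yfr <- data.frame(chrom = cfg$chrY_name, start = st, end = st + 100L,
                        barcode = rep(xy, ny), count = 1L,
                        stringsAsFactors = FALSE)
      frags <- rbind(frags, yfr)
    }
  }
  frags <- frags[order(frags$chrom, frags$start), ]
  rownames(frags) <- NULL
  frags
}

build_lr_specs <- function(cfg) {
  pathways <- c("WNT", "BMP", "inhibin-activin", "ephrin", "nectin",
                "IGF", "MDK", "DHH", "Notch")
  kinds <- c(rep("XX", cfg$n_lr_xx), rep("XY", cfg$n_lr_xy),
             rep("shared", cfg$n_lr_shared), rep("null", cfg$n_lr_null))
  n <- length(kinds)
  pair_id <- sprintf("LR%02d_%s", seq_len(n), kinds)
  hetero <- seq_len(n) %% 3 == 0
  lig <- lapply(seq_len(n), function(i) sprintf("Lig%02d", i))
  rec <- lapply(seq_len(n), function(i) {
    if (hetero[i]) sprintf("Rec%02d%s", i, c("a", "b")) else sprintf("Rec%02da", i)
  })
  data.frame(pair_id = pair_id, specificity = kinds,
             pathway = rep(pathways, length.out = n),
             ligand_subunits = I(lig), receptor_subunits = I(rec),
             stringsAsFactors = FALSE)
}

lr_table_from_specs <- function(specs) {
  data.frame(pair_id = specs$pair_id,
             ligand = vapply(specs$ligand_subunits, paste, "", collapse = ","),
             receptor = vapply(specs$receptor_subunits, paste, "", collapse = ","),
             pathway = specs$pathway, stringsAsFactors = FALSE)
}

#' Inject cross-population doublets
#'
#' A fraction of barcodes is replaced by the element-wise sum of two donor
#' cells drawn from different populations (in both modalities); flags and
#' donors are recorded.
#'
#' @param rna,atac CountMatrix pair over the same cells.
#' @param populations per-cell population labels.
#' @param rate doublet fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return list(rna, atac, is_doublet, donors).
#' @export
inject_doublets <- function(rna, atac, populations, rate, seed = 1L) {
  assert_that(rate >= 0 && rate < 1, "doublet rate must lie in [0, 1)")
  n <- ncol(rna)
  is_doublet <- logical(n)
  donors <- NULL
  if (rate > 0) {
    set.seed(as.integer(seed))
    n_dbl <- round(rate * n)
    targets <- sample.int(n, n_dbl)
    d1 <- integer(n_dbl); d2 <- integer(n_dbl)
    for (i in seq_len(n_dbl)) {
      d1[i] <- sample.int(n, 1)
      other <- which(populations != populations[d1[i]])
      d2[i] <- other[sample.int(length(other), 1)]
    }
    # one sparse selector multiply instead of per-column sub-assignment
    keep <- setdiff(seq_len(n), targets)
    sel <- Matrix::sparseMatrix(i = c(keep, d1, d2),
                                j = c(keep, targets, targets),
                                x = 1, dims = c(n, n))
    cn <- colnames(rna)
    rna <- rna %*% sel; colnames(rna) <- cn
    atac <- atac %*% sel; colnames(atac) <- cn
    is_doublet[targets] <- TRUE
    donors <- data.frame(cell_id = colnames(rna)[targets],
                         donor1 = colnames(rna)[d1], donor2 = colnames(rna)[d2],
                         pop1 = populations[d1], pop2 = populations[d2],
                         stringsAsFactors = FALSE)
  }
  list(rna = rna, atac = atac, is_doublet = is_doublet, donors = donors)
}
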