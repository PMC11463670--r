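#!/usr/bin/env Rscript
# Stage 1: generate the synthetic paired RNA/ATAC multiome.
# Emulates XX/XY fetal gonads at E11.5-E13.5 (PGCs, supporting cells, other
# somatic cells) with planted ground truth: chrY genes/peaks only in XY,
# sex-DE genes per stage, coupled peak-gene links, TF motifs in target
# enhancers, ligand-receptor pairs, and cross-population doublets.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
res <- advance("simulate")
sim <- res$sim
cat(sprintf("Simulated %d cells x %d genes (RNA) and %d peaks (ATAC); %d doublets.\n",
            ncol(sim$rna), nrow(sim$rna), nrow(sim$atac),
            sum(sim$truth$cells$doublet)))
cat(sprintf("Planted: %d sex-DE genes, %d peak-gene links, %d TF->target edges, %d LR pairs.\n",
            nrow(sim$truth$de_genes), nrow(sim$truth$links),
            nrow(sim$truth$tf_edges), nrow(sim$truth$lr_pairs)))
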