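#!/usr/bin/env Rscript
# Stage 4: dimensionality reduction (PCA on RNA; TF-IDF/LSI on ATAC, with
# component 1 flagged as the depth component), weighted joint neighbors,
# SNN-Louvain clustering (resolution 0.3), and MST pseudotime rooted at the
# E11.5 PGCs.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))
res <- advance("cluster")
cl <- res$cluster
cat(sprintf("%d cells in %d clusters; LSI depth correlation %.2f; %d branch node(s), %d terminal state(s).\n",
            length(cl$cells), length(unique(cl$clusters$labels)),
            cl$lsi$depth_cor, length(cl$pseudotime$branch_nodes),
            length(cl$pseudotime$terminal_nodes)))
cat("Tables: clusters.tsv, latents_rna.tsv\n")
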